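# Shared fixtures, all built in code.

rand_bipolar <- function(n) sample(c(-1, 1), n, replace = TRUE)

## A seeded random 5x5 template.
rand_template <- function(seed, label = NULL) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  template(matrix(rand_bipolar(25), 5), label = label)
}

## A seeded random symmetric zero-diagonal weight matrix (not necessarily
## Hebbian) for dynamics stress tests.
rand_symmetric_weights <- function(n) {
  W <- matrix(stats::rnorm(n * n), n)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  W
}

## The canonical stored pattern used across tests: the fall template the
## default generator produces at seed 1.
fall_template_seed1 <- function() {
  rec <- generate_activity("Fall", synth_config(), seed = 1)
  extract_template(binarize(fuse_axes(rec)), class_label = "Fall")
}

## Hand-rolled toy 9-axis input with known fused features (one row per case).
toy_imu_rows <- function() {
  m <- rbind(
    zero    = c(Gx = 0, Gy = 0, Gz = 0, Ax = 0, Ay = 0, Az = 0, Mx = 0, My = 0, Mz = 0),
    m4_case = c(Gx = 1, Gy = 0, Gz = 4, Ax = 2, Ay = 0, Az = 5, Mx = 0, My = 3, Mz = 0),
    gyro3   = c(Gx = 3, Gy = 3, Gz = 3, Ax = 0, Ay = 0, Az = 0, Mx = 0, My = 0, Mz = 0)
  )
  m
}
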