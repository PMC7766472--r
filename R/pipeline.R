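# End-to-end fall-detection pipeline:
#   synthesize -> fuse/binarize -> extract template -> Hebb-train on ONE fall
#   sample -> recall every recording's template (digital or analog backend)
#   -> cosine-classify -> confusion counts and accuracy.

#' Pipeline configuration
#'
#' Collects every stage's parameters with defaults matching the method's
#' operating point: 50 Hz sampling, thresholds `c(16,24,32,40,48)`,
#' per-feature pairing, 25 neurons, `eta = 1`, similarity threshold 0.8.
#'
#' @param synth a [synth_config()].
#' @param thresholds binarization thresholds, length 5, strictly increasing.
#' @param pairing threshold pairing mode, see [binarize()].
#' @param eta Hebbian learning rate.
#' @param backend `"digital"` (Hopfield recall) or `"analog"` (circuit
#'   simulation).
#' @param recall_mode update schedule for the digital backend.
#' @param circuit a [circuit_config()] for the analog backend.
#' @param class_threshold cosine-similarity decision threshold.
#' @param seed master seed (recall order / circuit noise; the generator uses
#'   `synth$seed`).
#' @param out_dir optional directory; when given, the training template, the
#'   weights and the report are written there as JSON.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = synth_config(),
                            thresholds = DEFAULT_THRESHOLDS,
                            pairing = "per-feature",
                            eta = 1,
                            backend = c("digital", "analog"),
                            recall_mode = "async",
                            circuit = circuit_config(),
                            class_threshold = 0.8,
                            seed = 42,
                            out_dir = NULL) {
  backend <- match.arg(backend)
  structure(list(synth = synth, thresholds = thresholds, pairing = pairing,
                 eta = eta, backend = backend, recall_mode = recall_mode,
                 circuit = circuit, class_threshold = class_threshold,
                 seed = seed, out_dir = out_dir),
            class = "pipeline_config")
}

## One recording -> its 5x5 template.
recording_template <- function(rec, config) {
  feat <- fuse_axes(rec)
  bin <- binarize(feat, config$thresholds, config$pairing)
  extract_template(bin, class_label = rec$label)
}

#' Run the full fall-detection pipeline
#'
#' Generates the synthetic dataset, trains the 25-neuron network on the
#' template of the *first* Fall recording (one-shot learning: one sensor
#' sample generates the standard pattern), then recalls every recording's
#' template through the chosen backend, classifies it against the stored
#' fall template by cosine similarity, and tallies the confusion counts.
#' Identical config and seeds give an identical report.
#'
#' @param config a [pipeline_config()].
#' @return a `pipeline_result`: list with `report`
#'   ([evaluate_decisions()] output), `decisions` (data frame: label, seed,
#'   similarity, positive), `template` (the stored fall template), `net`
#'   (the `hopfield` fit), `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dataset <- generate_dataset(config$synth)
  labels <- attr(dataset, "labels")
  train_idx <- which(labels == "Fall")[1L]
  if (is.na(train_idx)) stop("pipeline stage 'train': no Fall recording in dataset")
  fall_tpl <- recording_template(dataset[[train_idx]], config)
  net <- hopfield(fall_tpl, eta = config$eta)
  params <- if (config$backend == "analog") {
    map_weights_to_circuit(net, config$circuit)
  }
  rows <- lapply(seq_along(dataset), function(k) {
    tpl <- recording_template(dataset[[k]], config)
    recalled <- if (config$backend == "digital") {
      recall(net, tpl$vector, mode = config$recall_mode,
             seed = config$seed + k)$state
    } else {
      simulate_circuit(params, config$circuit, tpl$vector,
                       seed = config$seed + k)$state
    }
    cls <- classify_sample(recalled, list(Fall = fall_tpl),
                           threshold = config$class_threshold)
    data.frame(label = labels[k], seed = dataset[[k]]$seed,
               similarity = cls$similarities[["Fall"]],
               positive = cls$positive)
  })
  decisions <- do.call(rbind, rows)
  report <- evaluate_decisions(decisions$label, decisions$positive)
  result <- structure(list(report = report, decisions = decisions,
                           template = fall_tpl, net = net, config = config),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_template_json(fall_tpl, file.path(config$out_dir, "fall_template.json"))
    write_weights_json(net, file.path(config$out_dir, "weights.json"))
    utils::write.csv(decisions, file.path(config$out_dir, "decisions.csv"),
                     row.names = FALSE)
    jsonlite::write_json(unclass(report), file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> backend = %s, %d recordings\n",
              x$config$backend, nrow(x$decisions)))
  print(x$report)
  invisible(x)
}
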