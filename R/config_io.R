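# Model configuration YAML round-trip and runtime checkpoints.

#' Write a model configuration to YAML.
#'
#' The file records class count, width/depth multipliers, image size,
#' anchors, and (when present) the `c3f_rn` block with `depth`, `n_heads`,
#' `win_size`, `patch_size`.
#' @param cfg a [model_config()]
#' @param path output file
#' @export
write_model_config <- function(cfg, path) {
  obj <- list(nc = cfg$nc, width_mult = cfg$width_mult, depth_mult = cfg$depth_mult,
              img_size = cfg$img_size,
              anchors = lapply(cfg$anchors, function(a) as.vector(t(a))))
  if (!is.null(cfg$c3f_rn)) obj$c3f_rn <- cfg$c3f_rn
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a model configuration from YAML.
#' @param path file written by [write_model_config()]
#' @return a [model_config()]
#' @export
read_model_config <- function(path) {
  obj <- yaml::read_yaml(path)
  anchors <- lapply(obj$anchors, function(v) matrix(as.numeric(v), ncol = 2, byrow = TRUE))
  model_config(nc = obj$nc, width_mult = obj$width_mult,
               depth_mult = obj$depth_mult, img_size = obj$img_size,
               c3f_rn = obj$c3f_rn, anchors = anchors)
}

#' Save model weights, buffers and configuration to a checkpoint file.
#' @param model a built model
#' @param path destination (`.rds`)
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(cfg = model$cfg, variant = model$variant,
               widths = model$widths, strides_conf = model$strides_conf,
               params = as.list(model$env$params),
               buffers = as.list(model$env$buffers)), path)
  invisible(path)
}

#' Restore a model from a checkpoint file.
#' @param path file written by [save_checkpoint()]
#' @return a model with weights in place
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- if (identical(ck$variant, "toy")) {
    toy_detector(widths = ck$widths, img_size = ck$cfg$img_size, nc = ck$cfg$nc,
                 anchors = ck$cfg$anchors, strides_conf = ck$strides_conf)
  } else if (identical(ck$variant, "c3f_rn")) {
    assemble_yolo_ginseng(ck$cfg)
  } else {
    assemble_baseline(ck$cfg)
  }
  for (nm in names(ck$params)) model$env$params[[nm]] <- ck$params[[nm]]
  for (nm in names(ck$buffers)) model$env$buffers[[nm]] <- ck$buffers[[nm]]
  model
}
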