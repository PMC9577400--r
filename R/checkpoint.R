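# Model persistence: a checkpoint bundles the architecture configuration,
# the trained weights, and the frozen metadata schema (plus any
# normalization statistics), so featurization and model can never drift
# apart between training and inference. Configurations alone round-trip
# through YAML.

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the [fusion_config()], all parameters, the frozen
#' [meta_schema()] and the training-fold normalization statistics (when
#' metadata standardization was on).
#'
#' @param model A fitted [mmf_net()] or an [mmf_model()].
#' @param path Checkpoint file path.
#' @return `read_checkpoint` returns the restored model (predictions are
#'   bit-identical to the saved one); `write_checkpoint` returns `path`
#'   invisibly.
#' @export
write_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "mmf_model"))
  saveRDS(list(params = model$params, config = model$config,
               meta_width = model$meta_width,
               schema = model$schema, normalizer = model$normalizer,
               trace = model$trace, class = class(model)),
          path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- mmf_model(ck$config,
                     meta_width = if (ck$config$use_meta) ck$meta_width)
  model$params <- ck$params
  out <- c(unclass(model), list(schema = ck$schema, normalizer = ck$normalizer,
                                trace = ck$trace))
  class(out) <- ck$class
  out
}

#' Write / read a fusion configuration as YAML
#'
#' @param config A [fusion_config()].
#' @param path YAML file path.
#' @return `read_config` returns a [fusion_config()]; `write_config`
#'   returns `path` invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "fusion_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(fusion_config, yaml::read_yaml(path))
}
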