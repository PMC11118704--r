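#' Save a model checkpoint
#'
#' Writes the parameter arrays, the model configuration and the vocabulary
#' into a single versioned JSON file (text, portable; adequate for
#' desk-scale models).
#'
#' @param params parameter list.
#' @param cfg a `model_config`.
#' @param vocab the `vocabulary` the model was trained on.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(params, cfg, vocab, path) {
  payload <- list(
    format = "genophen-checkpoint", version = 1L,
    config = unclass(cfg),
    vocab = list(schema = vocab$schema, B = vocab$B),
    shapes = lapply(params, function(p)
      if (is.matrix(p)) dim(p) else length(p)),
    params = lapply(params, function(p) as.vector(p)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path file written by [save_checkpoint()].
#' @return list with `params`, `cfg` (a `model_config`), `vocab` (rebuilt
#'   from the stored schema).
#' @export
load_checkpoint <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "genophen-checkpoint"))
    stop("not a genophen checkpoint: ", path)
  cf <- payload$config
  cfg <- model_config(L = cf$L, h = cf$h, k = cf$k, B = cf$B, T = cf$T,
                      F = cf$F, vocab_size = cf$vocab_size,
                      ffn_mult = cf$ffn_mult, dropout = cf$dropout,
                      attn_scale = cf$attn_scale)
  params <- Map(function(v, shp) {
    if (length(shp) == 2L) matrix(v, shp[1L], shp[2L]) else as.numeric(v)
  }, payload$params, payload$shapes)
  schema <- lapply(payload$vocab$schema, as.character)
  vocab <- build_vocabulary(schema, payload$vocab$B)
  list(params = params, cfg = cfg, vocab = vocab)
}
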