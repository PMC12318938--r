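# Model checkpoints as JSON with the configuration embedded: portable, text
# only, full double precision.

#' Write / read a model checkpoint
#'
#' @param model a `wheatmoe_model`.
#' @param path JSON file path.
#' @return `read_model` returns the rebuilt model; `write_model` the path.
#' @export
write_model <- function(model, path) {
  params <- lapply(ls(model$P), function(n) {
    v <- model$P[[n]]
    list(name = n, dim = if (is.matrix(v)) dim(v) else length(v), values = as.numeric(v))
  })
  obj <- list(variant = model$variant, config = unclass(model$config), params = params)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- obj$config
  config <- model_config(profile = cfg$profile, d = cfg$d, n_enc_layers = cfg$n_enc_layers,
                         n_heads = cfg$n_heads, lstm_layers = cfg$lstm_layers,
                         n_experts = cfg$n_experts, top_k = cfg$top_k,
                         gate_hidden = cfg$gate_hidden, fusion_dims = unlist(cfg$fusion_dims),
                         ff_dim = cfg$ff_dim, dropout = as.list(cfg$dropout),
                         input_features = cfg$input_features, max_seq_len = cfg$max_seq_len,
                         renormalize_topk = cfg$renormalize_topk)
  model <- build_variant(obj$variant, config)
  for (i in seq_len(nrow(obj$params))) {
    n <- obj$params$name[i]
    dm <- unlist(obj$params$dim[i])
    v <- unlist(obj$params$values[i])
    model$P[[n]] <- if (length(dm) == 2) matrix(v, dm[1], dm[2]) else v
  }
  model
}
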