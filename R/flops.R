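# Analytic FLOP accounting for one forward pass of one sample. Convention:
# a dense m -> n map costs 2*m*n (multiply + accumulate); attention and the
# LSTM are tallied from their constituent matrix products; element-wise
# activations and normalizations are ignored. Sparse mixtures count k experts
# at the mean per-expert cost; dense mixtures count all experts, so the dense
# variant is strictly costlier for the same configuration.

dense_flops <- function(m, n) 2 * m * n

expert_flops <- function(e, d) {
  sp <- expert_spec(e, d)
  d_in <- 2 * d
  total <- 0
  for (w in sp$widths) {
    total <- total + dense_flops(d_in, w)
    d_in <- w
  }
  total + dense_flops(d_in, d)  # adapter
}

#' Analytic FLOP count per sample forward pass
#'
#' @param model a `wheatmoe_model` (or a variant name with `config` supplied).
#' @param t sequence length (months), default 10.
#' @param config used when `model` is a variant name.
#' @return FLOP count (numeric scalar).
#' @export
count_flops <- function(model, t = 10, config = NULL) {
  if (is.character(model)) {
    variant <- model
    cfg <- config %||% model_config()
  } else {
    variant <- model$variant
    cfg <- model$config
  }
  br <- variant_branches(variant)
  d <- cfg$d
  total <- t * dense_flops(cfg$input_features, d)  # embedding

  if (br$has_T) {
    per_layer <- 4 * t * dense_flops(d, d) +          # Q, K, V, output projections
      2 * dense_flops(t * t, d) +                     # scores and attention-weighted values
      t * dense_flops(d, cfg$ff_dim) + t * dense_flops(cfg$ff_dim, d)
    total <- total + cfg$n_enc_layers * per_layer
  }
  if (br$has_L) {
    Hd <- d %/% 2
    per_cell <- dense_flops(d, 4 * Hd) + dense_flops(Hd, 4 * Hd)
    total <- total + cfg$lstm_layers * 2 * t * per_cell
  }
  if (br$moe %in% c("sparse", "dense")) {
    total <- total + dense_flops(2 * d, cfg$gate_hidden) +
      dense_flops(cfg$gate_hidden, cfg$n_experts)
    all_costs <- vapply(0:(cfg$n_experts - 1L), expert_flops, numeric(1), d = d)
    total <- total + if (br$moe == "dense") sum(all_costs) else cfg$top_k * mean(all_costs)
  } else if (br$moe == "single") {
    total <- total + expert_flops(0, d)
  }
  fus_in <- d * ((br$moe != "none") + br$has_T + br$has_L)
  total + dense_flops(fus_in, cfg$fusion_dims[1]) +
    dense_flops(cfg$fusion_dims[1], cfg$fusion_dims[2]) +
    dense_flops(cfg$fusion_dims[2], 1)
}
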