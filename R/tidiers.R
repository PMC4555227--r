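# broom-style tidiers for fitted/model objects.

#' Tidy an energy model
#'
#' One row per (position, base) with the PWM weight, PFM frequency and
#' mismatch energy.
#'
#' @param x An `energy_model`.
#' @param ... Unused.
#' @return A tibble with columns `position`, `base`, `weight`, `freq`,
#'   `energy`.
#' @export
tidy.energy_model <- function(x, ...) {
  eps <- model_energies(x)
  tidyr::expand_grid(position = seq_len(ncol(x$pwm)), base = BASES) %>%
    mutate(weight = x$pwm[cbind(match(.data$base, BASES), .data$position)],
           freq = x$pfm[cbind(match(.data$base, BASES), .data$position)],
           energy = eps[cbind(match(.data$base, BASES), .data$position)])
}

#' Summarise an energy model
#'
#' @param x An `energy_model`.
#' @param ... Unused.
#' @return One-row tibble: model `name`, motif `length`, `mu`, `pseudo`,
#'   total information content (bits) and the consensus sequence of the
#'   matrix.
#' @export
glance.energy_model <- function(x, ...) {
  ic <- sum(apply(x$pfm, 2, function(f) 2 + sum(f * log2(f + 1e-12))))
  tibble(name = x$name, length = ncol(x$pwm), mu = x$mu, pseudo = x$pseudo,
         information_bits = ic,
         consensus = paste(BASES[apply(x$pwm, 2, which.max)], collapse = ""))
}

#' Summarise a cooperative-call table
#'
#' @param x A `coop_calls` tibble from [call_cooperative()].
#' @param ... Unused.
#' @return One-row tibble: region and call counts plus the thresholds
#'   used.
#' @export
glance.coop_calls <- function(x, ...) {
  th <- attr(x, "thresholds")
  tibble(n_regions = nrow(x), n_called = sum(x$is_cooperative),
         fdr_coop = unname(th["fdr_coop"]),
         fdr_single = unname(th["fdr_single"]))
}
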