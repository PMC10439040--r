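# Parameter validation for the core model and the variability layer.
# Core parameters: boundary separation a > 0, drift rate v, relative starting
# point 0 < w < 1, non-decision time t0 >= 0; diffusion coefficient fixed at 1.

check_core <- function(a, v, w, t0 = 0) {
  if (!is.numeric(a) || length(a) != 1 || !is.finite(a) || a <= 0)
    stop("`a` (boundary separation) must be a finite number > 0", call. = FALSE)
  if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
    stop("`v` (drift rate) must be a finite number", call. = FALSE)
  if (!is.numeric(w) || length(w) != 1 || !is.finite(w) || w <= 0 || w >= 1)
    stop("`w` (relative starting point) must lie strictly in (0, 1)",
         call. = FALSE)
  if (!is.numeric(t0) || length(t0) != 1 || !is.finite(t0) || t0 < 0)
    stop("`t0` (non-decision time) must be a finite number >= 0", call. = FALSE)
  invisible(TRUE)
}

# Trial-to-trial variability: v ~ Normal(mu_nu, s_nu), w ~ Uniform(mu_w -
# s_w/2, mu_w + s_w/2), t0 ~ Uniform(min_t0, min_t0 + s_t0).
check_variability <- function(a, mu_nu, s_nu, mu_w, s_w, min_t0, s_t0) {
  check_core(a, mu_nu, mu_w, min_t0)
  for (nm in c("s_nu", "s_w", "s_t0")) {
    val <- get(nm)
    if (!is.numeric(val) || length(val) != 1 || !is.finite(val) || val < 0)
      stop(sprintf("`%s` must be a finite number >= 0", sub("_", "", nm)),
           call. = FALSE)
  }
  if (s_w > 0 && (mu_w - s_w / 2 <= 0 || mu_w + s_w / 2 >= 1))
    stop("starting-point variability out of range: w support ",
         sprintf("[%.4f, %.4f] must lie inside (0, 1)",
                 mu_w - s_w / 2, mu_w + s_w / 2), call. = FALSE)
  invisible(TRUE)
}

check_precision <- function(precision) {
  if (!is.numeric(precision) || length(precision) != 1 ||
      !is.finite(precision) || precision <= 0 || precision > 1e-3)
    stop("`precision` must lie in (0, 1e-3]", call. = FALSE)
  invisible(TRUE)
}

check_bound <- function(bound) {
  if (!is.numeric(bound) || length(bound) != 1 || is.na(bound) || bound <= 0)
    stop("`bound` (truncation from above) must be > 0 (possibly Inf)",
         call. = FALSE)
  invisible(TRUE)
}

match_response <- function(response, allow_both = TRUE) {
  choices <- if (allow_both) c("both", "upper", "lower") else c("upper", "lower")
  match.arg(response, choices)
}
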