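#' Spike-in calibration of read counts
#'
#' Fits the per-timepoint calibration line relating sequencing read counts
#' to known spike-in concentrations. Five control mRNAs at relative
#' concentrations 1, 10, 100, 1,000 and 10,000 span four decades, so the
#' line is fitted in log10-log10 space: `log10(concentration) ~
#' log10(count)`. The returned function maps a read count to a relative
#' abundance normalized so the most abundant control maps to 1.
#'
#' @param spikes Tibble with `relative_concentration` and `count` for one
#'   timepoint (zero-count controls are dropped from the fit).
#' @return A function `count -> relative abundance`, with the fitted slope
#'   and intercept attached as attributes.
#' @examples
#' sp <- tibble::tibble(relative_concentration = 10^(0:4),
#'                      count = 5 * 10^(0:4))
#' cal <- fit_spikein_calibration(sp)
#' cal(5e4)  # the top control's count -> 1
#' @export
fit_spikein_calibration <- function(spikes) {
  stopifnot(all(c("relative_concentration", "count") %in% names(spikes)))
  if (is.unsorted(spikes$relative_concentration, strictly = TRUE)) {
    spikes <- arrange(spikes, .data$relative_concentration)
  }
  usable <- spikes[spikes$count > 0, , drop = FALSE]
  if (nrow(usable) < 2L) {
    abort("spike-in calibration needs at least 2 controls with count > 0")
  }
  fit <- lm(log10(relative_concentration) ~ log10(count), data = usable)
  a <- unname(coef(fit)[1]); b <- unname(coef(fit)[2])
  top <- max(spikes$relative_concentration)
  f <- function(count) {
    out <- rep(0, length(count))
    pos <- count > 0
    out[pos] <- 10^(a + b * log10(count[pos])) / top
    out
  }
  attr(f, "slope") <- b
  attr(f, "intercept") <- a
  attr(f, "top_concentration") <- top
  f
}

#' Spike-in normalized abundance time series
#'
#' For each timepoint, calibrates variant read counts against that
#' timepoint's spike-in controls ([fit_spikein_calibration()]), then
#' divides by the variant's relative representation in the untransfected
#' IVT input library to correct for initial loading differences.
#'
#' @param raw_counts Tibble with `variant_id`, `timepoint_h`, `count`.
#' @param spikes Tibble with `timepoint_h`, `relative_concentration`,
#'   `count`.
#' @param input_library Tibble with `variant_id`, `count` (untransfected
#'   IVT library); variants absent from it are excluded with a warning.
#' @return An `abundance_series` tibble: `variant_id`, `timepoint_h`,
#'   `abundance`, sorted by variant and time.
#' @export
normalize_series <- function(raw_counts, spikes, input_library) {
  input <- input_library |>
    mutate(input_rel = .data$count / sum(.data$count)) |>
    select("variant_id", "input_rel")
  missing_v <- setdiff(unique(raw_counts$variant_id), input$variant_id)
  if (length(missing_v)) {
    warn(sprintf("%d variant(s) missing from the input library were excluded",
                 length(missing_v)))
  }
  zero_in <- input$variant_id[input$input_rel <= 0]
  if (length(zero_in)) {
    warn("variants with zero input-library counts were excluded")
    input <- input[input$input_rel > 0, , drop = FALSE]
  }
  out <- raw_counts |>
    inner_join(input, by = "variant_id") |>
    group_by(.data$timepoint_h) |>
    group_split() |>
    map(function(tp) {
      cal <- fit_spikein_calibration(
        spikes[spikes$timepoint_h == tp$timepoint_h[1], , drop = FALSE])
      mutate(tp, abundance = cal(.data$count) / .data$input_rel)
    }) |>
    bind_rows() |>
    select("variant_id", "timepoint_h", "abundance") |>
    arrange(.data$variant_id, .data$timepoint_h)
  class(out) <- c("abundance_series", class(out))
  out
}

#' Integrated mRNA abundance (area under the decay curve)
#'
#' Under simple production kinetics (`d protein / dt` proportional to mRNA
#' abundance), the time integral of mRNA abundance is proportional to total
#' protein output. Integrates normalized abundance from the first to the
#' last observed timepoint assuming linear changes between timepoints
#' (trapezoid rule; no extrapolation to t = 0).
#'
#' @param series An [normalize_series()] tibble, or any tibble with
#'   `timepoint_h` and `abundance` (optionally grouped by `variant_id`).
#' @return One row per variant: `variant_id`, `auc` (hours x abundance
#'   units). For a single-variant input without `variant_id`, a plain
#'   number.
#' @examples
#' integrate_abundance(tibble::tibble(
#'   timepoint_h = c(0.5, 1, 2, 4, 8, 24),
#'   abundance = c(1, 0.5, 0.25, 0.125, 0.0625, 0)))  # 2.0
#' @export
integrate_abundance <- function(series) {
  auc1 <- function(t, y) {
    if (length(t) < 2L) abort("need at least 2 timepoints to integrate")
    ord <- order(t)
    pracma::trapz(t[ord], y[ord])
  }
  if (!"variant_id" %in% names(series)) {
    return(auc1(series$timepoint_h, series$abundance))
  }
  series |>
    group_by(.data$variant_id) |>
    summarise(auc = auc1(.data$timepoint_h, .data$abundance),
              .groups = "drop")
}

#' Single-exponential decay fit and biphasic misfit diagnostic
#'
#' Nonlinear least squares of `A * exp(-k * t)` (initialized from a
#' log-linear regression), reporting the fit RMSE as a diagnostic: decay
#' that is biphasic — a fast early phase and a slow late phase — cannot be
#' fit accurately by a single exponential and leaves a large residual.
#'
#' @param series Tibble with `timepoint_h` and `abundance` for one variant
#'   (at least 3 positive-abundance timepoints).
#' @return An `exp_decay_fit` list: `A`, `k`, `rmse`, `converged`,
#'   `fitted` tibble.
#' @export
fit_single_exponential <- function(series) {
  t <- series$timepoint_h
  y <- series$abundance
  if (length(t) < 3L) abort("need at least 3 timepoints")
  pos <- y > 0
  if (sum(pos) < 2L) abort("need positive abundances to initialize the fit")
  init <- lm(log(y[pos]) ~ t[pos])
  A0 <- exp(unname(coef(init)[1]))
  k0 <- max(-unname(coef(init)[2]), 1e-6)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-k * t),
                      start = list(A = A0, k = k0),
                      lower = c(A = 0, k = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    res <- list(A = A0, k = k0, rmse = sqrt(mean((A0 * exp(-k0 * t) - y)^2)),
                converged = FALSE,
                fitted = tibble(timepoint_h = t, abundance = y,
                                fitted = A0 * exp(-k0 * t)))
  } else {
    cf <- coef(fit)
    yhat <- unname(cf["A"]) * exp(-unname(cf["k"]) * t)
    res <- list(A = unname(cf["A"]), k = unname(cf["k"]),
                rmse = sqrt(mean((yhat - y)^2)), converged = TRUE,
                fitted = tibble(timepoint_h = t, abundance = y,
                                fitted = yhat))
  }
  structure(res, class = "exp_decay_fit")
}

#' @export
print.exp_decay_fit <- function(x, ...) {
  cat(sprintf("<exp_decay_fit> A = %.4g, k = %.4g /h, RMSE = %.4g%s\n",
              x$A, x$k, x$rmse,
              if (!x$converged) " (not converged)" else ""))
  invisible(x)
}

#' @export
tidy.exp_decay_fit <- function(x, ...) {
  tibble(term = c("A", "k"), estimate = c(x$A, x$k))
}

#' @export
glance.exp_decay_fit <- function(x, ...) {
  tibble(A = x$A, k = x$k, rmse = x$rmse, converged = x$converged)
}

#' @export
autoplot.exp_decay_fit <- function(object, ...) {
  ggplot2::ggplot(object$fitted, ggplot2::aes(x = .data$timepoint_h)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$abundance)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::labs(x = "time (h)", y = "normalized abundance") +
    ggplot2::theme_minimal()
}

#' Ribosome-free to total mRNA ratio
#'
#' Divides a variant's depth-normalized read count in the ribosome-free
#' fraction by its depth-normalized count in the total-RNA library. High
#' values indicate mRNA not engaged by any ribosome — translationally
#' inactive material that MRL (which only considers loaded mRNA) cannot
#' see.
#'
#' @param free_count,total_count Read counts (vectors align by position).
#' @param free_depth,total_depth Library sizes used for depth
#'   normalization; by default the sums of the supplied counts.
#' @return Numeric vector of ratios.
#' @export
free_to_total_ratio <- function(free_count, total_count,
                                free_depth = max(sum(free_count), 1),
                                total_depth = max(sum(total_count), 1)) {
  if (any(total_count <= 0)) {
    abort("total_count must be positive for every variant")
  }
  (free_count / free_depth) / (total_count / total_depth)
}
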