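#' Quartile convention used throughout the summaries
#'
#' Default is linear interpolation at position `q * (n + 1)` (R's
#' `quantile(type = 6)`), selectable via `qtype`.
#' @noRd
.quartiles <- function(x, qtype = 6) {
  stats::quantile(x, c(0.25, 0.5, 0.75), type = qtype, names = FALSE)
}

#' Per-label summary of fitted optical parameters
#'
#' Median and 25th/75th percentiles of one parameter per tissue label, the
#' standard per-class summary of a fits table.
#'
#' @param fits data.frame as from [batch_fit()] (needs columns `label`,
#'   `ok`, and the chosen parameter).
#' @param parameter `"mu"` or `"i0_normalized"` (any numeric column works).
#' @param qtype quantile type (see [stats::quantile()]); default 6.
#' @return data.frame with columns `label`, `parameter`, `median`, `q25`,
#'   `q75`, `n`; labels with zero successful fits are omitted with a
#'   message.
#' @export
summarize_by_label <- function(fits, parameter = "mu", qtype = 6) {
  stopifnot(is.data.frame(fits), nrow(fits) > 0,
            parameter %in% names(fits), "label" %in% names(fits))
  ok <- if ("ok" %in% names(fits)) fits$ok else rep(TRUE, nrow(fits))
  labs <- unique(fits$label)
  rows <- lapply(labs, function(l) {
    v <- fits[[parameter]][ok & fits$label == l]
    v <- v[is.finite(v)]
    if (!length(v)) {
      message("label '", l, "' has no successful fits; omitted")
      return(NULL)
    }
    q <- .quartiles(v, qtype)
    data.frame(label = l, parameter = parameter, median = q[2],
               q25 = q[1], q75 = q[3], n = length(v),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Between-system relative-difference statistic
#'
#' For every ordered pair of distinct tissue labels (x, y), the tissue
#' contrast of system A relative to system B:
#' \deqn{\rho_{xy} = \frac{m_A(x) / m_A(y)}{m_B(x) / m_B(y)}}
#' where `m` are the per-label medians of one optical parameter. The set of
#' ratios is reciprocal-closed (both orderings of every pair are included);
#' its median and quartiles quantify how similarly the two systems rank and
#' scale the tissue classes — identical relative contrasts give a median of
#' exactly 1 regardless of the absolute calibration of either system.
#'
#' @param summary_a,summary_b either a summary data.frame from
#'   [summarize_by_label()] or a named numeric vector of per-label medians.
#'   Both must cover the same set of at least two labels.
#' @param qtype quantile type for the ratio quartiles (default 6).
#' @return object of class `system_comparison`: `ratios` (named vector, one
#'   per ordered label pair), `median`, `q25`, `q75`, `labels`,
#'   `n_pairs`.
#' @examples
#' ref <- reference_optical_properties()
#' a <- setNames(ref$mu[ref$system == "sd"], ref$label[ref$system == "sd"])
#' b <- setNames(ref$mu[ref$system == "ss"], ref$label[ref$system == "ss"])
#' compare_systems(a, b)   # median 1.00 [0.76; 1.32]
#' @export
compare_systems <- function(summary_a, summary_b, qtype = 6) {
  a <- .as_medians(summary_a)
  b <- .as_medians(summary_b)
  labs <- intersect(names(a), names(b))
  if (length(labs) < 2) {
    stop("compare_systems needs at least two labels common to both systems",
         call. = FALSE)
  }
  if (!setequal(names(a), names(b))) {
    warning("label sets differ; using the ", length(labs),
            " common labels only")
  }
  a <- a[labs]; b <- b[labs]
  drop <- labs[a == 0 | b == 0]
  if (length(drop)) {
    warning("label(s) with zero median excluded from pairing: ",
            paste(drop, collapse = ", "))
    labs <- setdiff(labs, drop)
    a <- a[labs]; b <- b[labs]
    if (length(labs) < 2) {
      stop("fewer than two labels with nonzero medians remain", call. = FALSE)
    }
  }
  pairs <- expand.grid(x = labs, y = labs, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$x != pairs$y, ]
  ratios <- (a[pairs$x] / a[pairs$y]) / (b[pairs$x] / b[pairs$y])
  names(ratios) <- paste(pairs$x, pairs$y, sep = " / ")
  q <- .quartiles(ratios, qtype)
  structure(list(ratios = ratios, median = q[2], q25 = q[1], q75 = q[3],
                 labels = labs, n_pairs = length(ratios), qtype = qtype),
            class = "system_comparison")
}

.as_medians <- function(x) {
  if (is.numeric(x) && !is.null(names(x))) return(x)
  if (is.data.frame(x) && all(c("label", "median") %in% names(x))) {
    return(stats::setNames(x$median, x$label))
  }
  stop("expected a named numeric vector of medians or a summarize_by_label() table",
       call. = FALSE)
}

#' @export
print.system_comparison <- function(x, ...) {
  cat(sprintf("Between-system relative difference over %d label pairs (%d labels)\n",
              x$n_pairs, length(x$labels)))
  cat(sprintf("  median %.2f [%.2f; %.2f]\n", x$median, x$q25, x$q75))
  invisible(x)
}
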