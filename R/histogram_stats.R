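# Per-individual normalized histograms and the per-bin between-class
# comparison (pooled two-sample t, Bonferroni correction, Hedges' g).

#' Bin family for an index
#'
#' Fixed bin families: distance in 50 cm bins from 0 to `distance_max`
#' (default 1350 cm, just above the diagonal of a 10 m x 8.5 m hall), angle
#' and approaching angle in 18 bins of 10 degrees over `[0, 180]`, angular
#' momentum in 10 bins of width 0.1 over `[0, 1]`. Bins are labelled by their
#' upper edge, matching the convention "the bin of 50 cm" / "of 20 degrees" /
#' "of 0.8". All bins are right-closed and the first is closed on both sides,
#' so 0 falls in the first bin.
#'
#' Distance samples beyond the last edge (impossible inside the arena, but
#' possible for synthetic data) are counted in an overflow bin that enters the
#' normalization but is excluded from testing (`testable = FALSE`).
#'
#' @param index_kind one of `"distance"`, `"angle"`, `"approach_angle"`,
#'   `"momentum"`.
#' @param distance_max upper edge of the last regular distance bin (cm).
#' @return an object of class `bin_spec`: list with `index_kind`, `edges`,
#'   `labels`, `testable` (logical per bin), `n_bins` (count of testable
#'   bins, the Bonferroni family size).
#' @export
bin_spec <- function(index_kind = c("distance", "angle", "approach_angle",
                                    "momentum"),
                     distance_max = 1350) {
  index_kind <- match.arg(index_kind)
  if (index_kind == "distance") {
    edges <- seq(0, distance_max, by = 50)
    labels <- c(as.character(edges[-1]), "overflow")
    edges <- c(edges, Inf)
    testable <- c(rep(TRUE, length(edges) - 2L), FALSE)
  } else if (index_kind == "momentum") {
    edges <- seq(0, 1, by = 0.1)
    labels <- format(edges[-1], trim = TRUE)
    testable <- rep(TRUE, 10)
  } else {
    edges <- seq(0, 180, by = 10)
    labels <- as.character(edges[-1])
    testable <- rep(TRUE, 18)
  }
  structure(list(index_kind = index_kind, edges = edges, labels = labels,
                 testable = testable, n_bins = sum(testable)),
            class = "bin_spec")
}

#' Normalized histogram of one individual's samples
#'
#' Counts per bin divided by the individual's total sample count, so every
#' individual contributes a probability vector regardless of how long or how
#' actively it moved. `NA` samples are dropped first.
#'
#' @param x numeric samples for one individual.
#' @param spec a [bin_spec()].
#' @return object of class `child_histogram`: list with `frequencies` (named,
#'   summing to 1 when any sample exists), `counts`, `n_samples`, `spec`.
#' @export
per_child_histogram <- function(x, spec) {
  x <- x[!is.na(x)]
  if (length(x)) {
    cut_idx <- cut(x, breaks = spec$edges, right = TRUE, include.lowest = TRUE,
                   labels = FALSE)
    if (anyNA(cut_idx)) stop("samples outside the bin family range")
    counts <- tabulate(cut_idx, nbins = length(spec$labels))
    freqs <- counts / length(x)
  } else {
    counts <- rep(0L, length(spec$labels))
    freqs <- rep(0, length(spec$labels))
  }
  names(counts) <- names(freqs) <- spec$labels
  structure(list(frequencies = freqs, counts = counts, n_samples = length(x),
                 spec = spec),
            class = "child_histogram")
}

#' Per-individual sample sets for each index
#'
#' For pairwise indices, individual i's sample set pools its values against
#' every partner over all valid frames (so each unordered distance appears in
#' both members' sets); for angular momentum it is the individual's own valid
#' frames.
#'
#' @param ps a `pair_series` (distance or angle).
#' @return named list of numeric sample vectors.
#' @export
pair_samples_by_child <- function(ps) {
  out <- lapply(seq_along(ps$ids), function(i) {
    v <- as.vector(ps$values[, i, -i])
    v[!is.na(v)]
  })
  names(out) <- ps$ids
  out
}

#' @rdname pair_samples_by_child
#' @param momentum a `momentum_series`.
#' @export
momentum_samples_by_child <- function(momentum) {
  ids <- colnames(momentum)
  out <- lapply(ids, function(id) {
    v <- momentum[, id]
    v[!is.na(v)]
  })
  names(out) <- ids
  out
}

#' Histograms for every individual of a session
#'
#' @param samples named list of per-individual sample vectors.
#' @param spec a [bin_spec()].
#' @param drop_empty drop individuals with zero samples (used for the
#'   approaching angle, where uninvolved individuals carry no information).
#' @return named list of `child_histogram` objects.
#' @export
session_histograms <- function(samples, spec, drop_empty = FALSE) {
  hists <- lapply(samples, per_child_histogram, spec = spec)
  if (drop_empty) hists <- Filter(function(h) h$n_samples > 0, hists)
  hists
}

#' Class-level mean histogram with standard errors
#'
#' Unweighted mean over individuals of the per-individual normalized
#' frequencies, with the standard error of that mean per bin.
#'
#' @param histograms list of `child_histogram` objects (>= 2).
#' @return data frame `bin, mean, se, n`.
#' @export
class_mean_histogram <- function(histograms) {
  if (length(histograms) == 0L) {
    return(data.frame(bin = character(), mean = numeric(), se = numeric(),
                      n = integer()))
  }
  F <- do.call(rbind, lapply(histograms, function(h) h$frequencies))
  data.frame(bin = colnames(F),
             mean = colMeans(F),
             se = apply(F, 2, sd) / sqrt(nrow(F)),
             n = nrow(F),
             row.names = NULL)
}

#' Per-bin between-class comparison
#'
#' Pooled-variance two-sample Student t-test on the per-individual normalized
#' frequencies of one bin, with Bonferroni correction over the bin family and
#' the pooled-SD standardized mean difference as the effect size. The sign
#' convention puts class A first, so a negative t (and g) means class B sits
#' higher in that bin.
#'
#' Hedges' g is reported without the small-sample bias correction, which makes
#' the identity `|g| = |t| * sqrt(1/n_a + 1/n_b)` exact.
#'
#' @param freqs_a,freqs_b numeric vectors: one frequency per individual of
#'   class A and class B (each length >= 2).
#' @param n_bins_family Bonferroni family size (number of testable bins).
#' @return one-row data frame `mean_a, se_a, n_a, mean_b, se_b, n_b, t, df,
#'   p_raw, p_bonferroni, g`.
#' @export
compare_bin <- function(freqs_a, freqs_b, n_bins_family) {
  n_a <- length(freqs_a); n_b <- length(freqs_b)
  stopifnot(n_a >= 2, n_b >= 2)
  m_a <- mean(freqs_a); m_b <- mean(freqs_b)
  df <- n_a + n_b - 2L
  sp2 <- ((n_a - 1) * stats::var(freqs_a) + (n_b - 1) * stats::var(freqs_b)) / df
  if (sp2 == 0) {
    if (m_a == m_b) {
      tval <- 0; g <- 0; p <- 1
    } else {
      tval <- sign(m_a - m_b) * Inf; g <- tval; p <- 0
    }
  } else {
    se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
    tval <- (m_a - m_b) / se
    g <- (m_a - m_b) / sqrt(sp2)
    p <- 2 * pt(-abs(tval), df)
  }
  data.frame(mean_a = m_a, se_a = sd(freqs_a) / sqrt(n_a), n_a = n_a,
             mean_b = m_b, se_b = sd(freqs_b) / sqrt(n_b), n_b = n_b,
             t = tval, df = df, p_raw = p,
             p_bonferroni = min(1, p * n_bins_family), g = g)
}

#' Between-class comparison over a whole bin family
#'
#' Runs [compare_bin()] for every testable bin of the family on the
#' per-individual histograms of the two classes.
#'
#' @param hists_a,hists_b lists of `child_histogram` objects (class A is
#'   conventionally the younger class, so the printed sign convention holds).
#' @param spec the shared [bin_spec()].
#' @param alpha significance level applied to the corrected p-values.
#' @return object of class `group_comparison`: data frame with one row per
#'   testable bin (`index, bin, ...` columns of [compare_bin()], plus
#'   `significant`).
#' @export
compare_classes <- function(hists_a, hists_b, spec, alpha = 0.05) {
  if (length(hists_a) < 2 || length(hists_b) < 2) {
    warning("fewer than 2 individuals with samples in a class; the ",
            spec$index_kind, " comparison is empty")
    out <- data.frame(index = character(), bin = character(),
                      mean_a = numeric(), se_a = numeric(), n_a = integer(),
                      mean_b = numeric(), se_b = numeric(), n_b = integer(),
                      t = numeric(), df = numeric(), p_raw = numeric(),
                      p_bonferroni = numeric(), g = numeric(),
                      significant = logical())
    class(out) <- c("group_comparison", "data.frame")
    return(out)
  }
  Fa <- do.call(rbind, lapply(hists_a, function(h) h$frequencies))
  Fb <- do.call(rbind, lapply(hists_b, function(h) h$frequencies))
  rows <- lapply(which(spec$testable), function(b) {
    cbind(data.frame(index = spec$index_kind, bin = spec$labels[b]),
          compare_bin(Fa[, b], Fb[, b], spec$n_bins))
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p_bonferroni < alpha
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' Effect size implied by a t statistic
#'
#' Algebraic identity linking the pooled-t statistic and the uncorrected
#' pooled-SD standardized mean difference: `|g| = |t| * sqrt(1/n_a + 1/n_b)`.
#' Useful as an internal consistency check of reported (t, g) pairs.
#'
#' @param t t statistic.
#' @param n_a,n_b group sizes.
#' @return implied `|g|`.
#' @export
hedges_g_from_t <- function(t, n_a, n_b) abs(t) * sqrt(1 / n_a + 1 / n_b)
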