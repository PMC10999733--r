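# Per-sample histograms, group aggregation with SE bands, histogram peaks
# and the t-tests on per-sample peaks.
#
# Unit-of-analysis rule: every significance test consumes exactly one number
# per biological sample - the histogram peak - never pooled fiber samples.

#' Per-sample theta and k_theta histograms
#'
#' Weighted, area-normalized histograms over fixed bins; theta binning is
#' circular on [0, 180). The per-sample histogram peaks are the inputs to
#' all group statistics.
#'
#' @param samples a `fiber_samples` data.frame with `theta_deg`, optionally
#'   `k_theta` and `weight` columns.
#' @param bin_width_theta theta bin width in degrees (default 4, i.e. 45
#'   bins over the axial range).
#' @param bin_edges_ktheta curvature bin edges in 1/um (default 2.5e-4
#'   spacing spanning +-0.01; values outside are clamped into the end bins).
#' @param sample_id,surface_type,day,treatment metadata carried into the
#'   summary.
#' @param weighted use the coherence weights (default) or plain counts.
#' @return list of class `sample_summary`: `theta_hist` and `ktheta_hist`
#'   (each with `breaks`, `mids`, `density`), `theta_peak`, `ktheta_peak`,
#'   `n_points` and the metadata fields.
#' @export
sample_histograms <- function(samples, bin_width_theta = 4,
                              bin_edges_ktheta = seq(-0.01, 0.01, 2.5e-4),
                              sample_id = "sample", surface_type = NA,
                              day = NA, treatment = NA, weighted = TRUE) {
  if (nrow(samples) < 1) stop("empty-input: no fiber samples")
  stopifnot(180 %% bin_width_theta == 0)
  w <- if (weighted && !is.null(samples$weight)) samples$weight
       else rep(1, nrow(samples))
  th <- wrap_axial(samples$theta_deg)
  tbreaks <- seq(0, 180, by = bin_width_theta)
  tbin <- findInterval(th, tbreaks, rightmost.closed = FALSE,
                       all.inside = FALSE)
  tbin[tbin > length(tbreaks) - 1] <- length(tbreaks) - 1  # theta == 180-eps
  tcount <- accumulate_at(tbin, w, length(tbreaks) - 1)
  tdens <- tcount / (sum(tcount) * bin_width_theta)
  theta_hist <- list(breaks = tbreaks,
                     mids = tbreaks[-1] - bin_width_theta / 2,
                     density = tdens)
  ktheta_hist <- NULL
  ktheta_peak <- NA_real_
  if (!is.null(samples$k_theta)) {
    kb <- bin_edges_ktheta
    k <- pmin(pmax(samples$k_theta, kb[1] + 1e-15), kb[length(kb)] - 1e-15)
    kbin <- findInterval(k, kb, all.inside = TRUE)
    kcount <- accumulate_at(kbin, w, length(kb) - 1)
    kdens <- kcount / (sum(kcount) * diff(kb))
    ktheta_hist <- list(breaks = kb, mids = (kb[-1] + kb[-length(kb)]) / 2,
                        density = kdens)
    ktheta_peak <- peak_value(ktheta_hist, circular = FALSE)
  }
  structure(
    list(theta_hist = theta_hist, ktheta_hist = ktheta_hist,
         theta_peak = peak_value(theta_hist, circular = TRUE),
         ktheta_peak = ktheta_peak, n_points = nrow(samples),
         sample_id = sample_id, surface_type = surface_type, day = day,
         treatment = treatment),
    class = "sample_summary"
  )
}

#' Histogram peak position
#'
#' Centre of the maximal bin; ties are broken by the circular mean of the
#' tied bin centres (theta) or the arithmetic mean (k_theta). Optional
#' parabolic sub-bin refinement through the maximal bin and its neighbours.
#'
#' @param hist list with `mids` and `density` (as built by
#'   [sample_histograms()]).
#' @param circular treat the bin centres as axial angles.
#' @param refine parabolic sub-bin interpolation of the peak position.
#' @return peak position (degrees or 1/um).
#' @export
peak_value <- function(hist, circular = TRUE, refine = FALSE) {
  d <- hist$density
  if (length(d) == 0 || all(!is.finite(d))) stop("empty histogram")
  imax <- which(d == max(d))
  if (length(imax) > 1) {
    return(if (circular) axial_mean(hist$mids[imax])
           else mean(hist$mids[imax]))
  }
  peak <- hist$mids[imax]
  if (refine) {
    n <- length(d)
    il <- if (circular) ((imax - 2) %% n) + 1 else max(1, imax - 1)
    ir <- if (circular) (imax %% n) + 1 else min(n, imax + 1)
    y0 <- d[il]; y1 <- d[imax]; y2 <- d[ir]
    den <- y0 - 2 * y1 + y2
    if (il != imax && ir != imax && den < 0) {
      bw <- diff(hist$mids[1:2])
      peak <- peak + 0.5 * bw * (y0 - y2) / den
      if (circular) peak <- wrap_axial(peak)
    }
  }
  peak
}

#' Average histograms across the samples of one group
#'
#' Per-bin mean and standard error across samples (samples, not fiber
#' points, are the unit of analysis).
#'
#' @param summaries list of `sample_summary` objects from one group.
#' @param which `"theta"` or `"ktheta"`.
#' @return list with `mids`, `mean`, `se` (all per bin), `n`; with a single
#'   sample `se` is `NA` and `se_defined` is `FALSE`.
#' @export
group_average <- function(summaries, which = c("theta", "ktheta")) {
  which <- match.arg(which)
  stopifnot(length(summaries) >= 1)
  hists <- lapply(summaries, function(s) {
    s[[paste0(if (which == "theta") "theta" else "ktheta", "_hist")]]
  })
  mids <- hists[[1]]$mids
  for (h in hists) {
    if (!isTRUE(all.equal(h$mids, mids))) {
      stop("histograms must share identical bins")
    }
  }
  m <- do.call(rbind, lapply(hists, `[[`, "density"))
  n <- nrow(m)
  list(mids = mids, mean = colMeans(m),
       se = if (n >= 2) apply(m, 2, stats::sd) / sqrt(n)
            else rep(NA_real_, ncol(m)),
       n = n, se_defined = n >= 2)
}

#' Significance stars at the 0.05 / 0.005 / 0.001 levels
#'
#' @param p p-values.
#' @return character vector: `"n.s."`, `"*"`, `"**"` or `"***"`.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.005, "**",
         ifelse(p < 0.05, "*", "n.s.")))
}

#' One-sample t-test of histogram peaks against a reference value
#'
#' Classical one-sample t statistic on one peak per sample. With
#' `circular = TRUE` the peaks are first linearized as wrapped axial
#' differences from the reference (so a reference of 180 handles peaks just
#' above 0 correctly) and the test is of mean difference 0.
#'
#' @param peaks per-sample histogram peaks.
#' @param reference reference value (degrees or 1/um).
#' @param circular linearize on the axial circle before testing.
#' @return list with `t`, `df`, `p` (two-sided), `stars` (significance at
#'   the 0.05 / 0.005 / 0.001 levels), `mean`, `n`.
#' @export
one_sample_test <- function(peaks, reference, circular = FALSE) {
  peaks <- peaks[!is.na(peaks)]
  n <- length(peaks)
  if (n < 2) stop("need >= 2 peaks for a one-sample t-test")
  x <- if (circular) axial_diff(peaks, reference) else peaks - reference
  m <- mean(x); s <- stats::sd(x)
  t <- m / (s / sqrt(n))
  p <- if (s == 0) as.numeric(m == 0) else 2 * stats::pt(-abs(t), n - 1)
  if (s == 0 && m == 0) t <- 0
  list(t = t, df = n - 1, p = p, stars = significance_stars(p),
       mean = if (circular) wrap_axial(reference + m) else m + reference,
       n = n)
}

#' Two-sample t-test of histogram peaks between groups
#'
#' Equal-variance (pooled) two-sample t by default, Welch optionally. With
#' `circular = TRUE` both groups are linearized as wrapped axial
#' differences from the pooled axial mean.
#'
#' @param peaks_a,peaks_b per-sample peaks of the two groups.
#' @param welch use the Welch (unequal-variance) statistic.
#' @param circular linearize on the axial circle before testing.
#' @return list with `t`, `df`, `p`, `stars`, `mean_a`, `mean_b`, `n_a`,
#'   `n_b`.
#' @export
two_sample_test <- function(peaks_a, peaks_b, welch = FALSE,
                            circular = FALSE) {
  peaks_a <- peaks_a[!is.na(peaks_a)]; peaks_b <- peaks_b[!is.na(peaks_b)]
  na <- length(peaks_a); nb <- length(peaks_b)
  if (na < 2 || nb < 2) stop("need >= 2 peaks per group")
  if (circular) {
    centre <- axial_mean(c(peaks_a, peaks_b))
    a <- axial_diff(peaks_a, centre); b <- axial_diff(peaks_b, centre)
  } else {
    a <- peaks_a; b <- peaks_b
  }
  va <- stats::var(a); vb <- stats::var(b)
  if (welch) {
    se2 <- va / na + vb / nb
    t <- (mean(a) - mean(b)) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  }
  if (is.nan(t)) { t <- 0 }
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p, stars = significance_stars(p),
       mean_a = mean(a), mean_b = mean(b), n_a = na, n_b = nb)
}

#' Build the aggregate report
#'
#' Aggregates per-sample summaries into tidy tables: per-sample peaks,
#' per-bin group-averaged histograms with SE, one-sample tests of the theta
#' peaks against the group reference (90 for bridges, 180 for pores) and of
#' the k_theta peaks against `ktheta_reference`, and two-sample tests
#' between treatments at matching time points. Optionally writes
#' deterministic CSV/JSON files and simple SVG figures.
#'
#' @param summaries list of `sample_summary` objects.
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param ktheta_reference reference curvature for the one-sample test
#'   (1/um). Default 0: the curvature along the fiber direction is tested
#'   for being significantly different from zero.
#' @param figures also write SVG figures (histograms and peak box plots).
#' @return list of class `report_bundle` with data.frames `peaks`,
#'   `histograms`, `tests`; empty inputs yield an empty bundle with a
#'   warning.
#' @export
build_report <- function(summaries, out_dir = NULL, ktheta_reference = 0,
                         figures = FALSE) {
  if (length(summaries) == 0) {
    warning("no sample summaries; empty report")
    out <- list(peaks = data.frame(), histograms = data.frame(),
                tests = data.frame())
    class(out) <- "report_bundle"
    return(out)
  }
  peaks <- do.call(rbind, lapply(summaries, function(s) {
    data.frame(sample_id = s$sample_id,
               surface_type = as.character(s$surface_type),
               day = s$day, treatment = as.character(s$treatment),
               theta_peak = s$theta_peak, ktheta_peak = s$ktheta_peak,
               n_points = s$n_points, stringsAsFactors = FALSE)
  }))
  peaks <- peaks[order(peaks$surface_type, peaks$day, peaks$treatment,
                       peaks$sample_id), , drop = FALSE]
  rownames(peaks) <- NULL
  key <- interaction(peaks$surface_type, peaks$day, peaks$treatment,
                     drop = TRUE)
  hist_rows <- list(); test_rows <- list()
  for (g in levels(key)) {
    idx <- which(key == g)
    sums <- summaries[idx]
    ga <- group_average(sums, "theta")
    hist_rows[[length(hist_rows) + 1]] <- data.frame(
      group = g, quantity = "theta", mid = ga$mids, mean = ga$mean,
      se = ga$se, n = ga$n, stringsAsFactors = FALSE)
    if (!is.null(sums[[1]]$ktheta_hist)) {
      gk <- group_average(sums, "ktheta")
      hist_rows[[length(hist_rows) + 1]] <- data.frame(
        group = g, quantity = "ktheta", mid = gk$mids, mean = gk$mean,
        se = gk$se, n = gk$n, stringsAsFactors = FALSE)
    }
    st <- peaks$surface_type[idx[1]]
    ref <- if (identical(st, "pore")) 180 else 90
    if (length(idx) >= 2) {
      ot <- one_sample_test(peaks$theta_peak[idx], ref, circular = TRUE)
      test_rows[[length(test_rows) + 1]] <- data.frame(
        group = g, test = "one_sample_theta", reference = ref, t = ot$t,
        df = ot$df, p = ot$p, stars = ot$stars, stringsAsFactors = FALSE)
      if (any(is.finite(peaks$ktheta_peak[idx]))) {
        kt <- one_sample_test(peaks$ktheta_peak[idx], ktheta_reference)
        test_rows[[length(test_rows) + 1]] <- data.frame(
          group = g, test = "one_sample_ktheta", reference = ktheta_reference,
          t = kt$t, df = kt$df, p = kt$p, stars = kt$stars,
          stringsAsFactors = FALSE)
      }
    }
  }
  # two-sample comparisons between treatments at matched surface/day
  sd_key <- unique(peaks[, c("surface_type", "day")])
  for (i in seq_len(nrow(sd_key))) {
    sub <- peaks[peaks$surface_type == sd_key$surface_type[i] &
                   peaks$day %in% sd_key$day[i], ]
    trts <- unique(sub$treatment)
    if (length(trts) < 2) next
    cmb <- utils::combn(sort(trts), 2)
    for (j in seq_len(ncol(cmb))) {
      pa <- sub$theta_peak[sub$treatment == cmb[1, j]]
      pb <- sub$theta_peak[sub$treatment == cmb[2, j]]
      if (length(pa) < 2 || length(pb) < 2) next
      tt <- two_sample_test(pa, pb, circular = TRUE)
      test_rows[[length(test_rows) + 1]] <- data.frame(
        group = sprintf("%s.%s.%s_vs_%s", sd_key$surface_type[i],
                        sd_key$day[i], cmb[1, j], cmb[2, j]),
        test = "two_sample_theta", reference = NA_real_, t = tt$t,
        df = tt$df, p = tt$p, stars = tt$stars, stringsAsFactors = FALSE)
    }
  }
  out <- list(
    peaks = peaks,
    histograms = if (length(hist_rows)) do.call(rbind, hist_rows)
                 else data.frame(),
    tests = if (length(test_rows)) do.call(rbind, test_rows)
            else data.frame()
  )
  class(out) <- "report_bundle"
  if (!is.null(out_dir)) write_report(out, out_dir, figures = figures)
  out
}

#' Write a report bundle to disk
#'
#' Deterministic CSV tables, a JSON summary and (optionally) SVG figures.
#'
#' @param report a `report_bundle`.
#' @param out_dir output directory (created if needed).
#' @param figures also write SVG figures.
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir, figures = FALSE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  utils::write.csv(report$peaks, file.path(out_dir, "peaks.csv"),
                   row.names = FALSE)
  utils::write.csv(report$histograms, file.path(out_dir, "histograms.csv"),
                   row.names = FALSE)
  utils::write.csv(report$tests, file.path(out_dir, "tests.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(n_samples = nrow(report$peaks),
         groups = unique(as.character(
           interaction(report$peaks$surface_type, report$peaks$day,
                       report$peaks$treatment, drop = TRUE))),
         tests = report$tests),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE, na = "null")
  if (figures && nrow(report$peaks) > 0) {
    grDevices::svg(file.path(out_dir, "theta_peaks.svg"), width = 7,
                   height = 5)
    graphics::boxplot(theta_peak ~ interaction(surface_type, day,
                                               treatment, drop = TRUE),
                      data = report$peaks, las = 2,
                      ylab = "theta peak (deg)", xlab = "")
    grDevices::dev.off()
    th <- report$histograms[report$histograms$quantity == "theta", ]
    if (nrow(th) > 0) {
      grDevices::svg(file.path(out_dir, "theta_histograms.svg"), width = 7,
                     height = 5)
      groups <- unique(th$group)
      graphics::plot(NA, xlim = c(0, 180), ylim = c(0, max(th$mean + ifelse(
        is.na(th$se), 0, th$se))), xlab = "theta (deg)", ylab = "density")
      for (gi in seq_along(groups)) {
        sub <- th[th$group == groups[gi], ]
        graphics::lines(sub$mid, sub$mean, col = gi)
      }
      graphics::legend("topright", legend = groups,
                       col = seq_along(groups), lty = 1, cex = 0.6)
      grDevices::dev.off()
    }
  }
  invisible(out_dir)
}
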