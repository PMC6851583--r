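## Population-dynamics estimators on abundance time series, and the
## per-timepoint statistical-testing protocol (Type II one-way ANOVA with
## Tukey-adjusted pairs; Welch t tests for two-group contrasts).

#' Log2 fold change relative to a reference abundance
#'
#' \eqn{n_t = (\ln N_t - \ln N_i) / \ln 2}: the number of generations under
#' exponential growth. The customary references are dawn (-3.5 h) for host
#' cells and the first post-inoculation sample (0.5 h) for virions.
#'
#' @param values abundances \eqn{N_t} (> 0).
#' @param reference the reference abundance \eqn{N_i} (> 0), or, when
#'   \code{times} is given, the reference time whose value is used.
#' @param times optional sampling times matching \code{values}.
#' @return Numeric vector of log2 fold changes; non-positive abundances
#'   yield \code{NA} with a warning.
#' @examples
#' log2FoldChange(c(1e6, 2e6, 5e6), reference = 1e6)
#' @export
log2FoldChange <- function(values, reference, times = NULL) {
  if (!is.null(times)) {
    j <- which(abs(times - reference) < 1e-8)
    if (length(j) != 1)
      stop("reference time not found (exactly once) in times")
    reference <- values[j]
  }
  if (!is.finite(reference) || reference <= 0)
    stop("reference abundance must be > 0")
  bad <- !is.finite(values) | values <= 0
  if (any(bad)) {
    warning("non-positive abundances: log2 fold change undefined, set NA")
    values[bad] <- NA_real_
  }
  (log(values) - log(reference)) / log(2)
}

#' Specific growth rate over an interval
#'
#' \eqn{\mu = \ln(N_{t_1}/N_{t_0}) / \Delta t}, converted to 1/d from an
#' hourly time axis. Negative values are net mortality.
#'
#' @param values abundances.
#' @param times sampling times (h) matching \code{values}.
#' @param t0,t1 interval endpoints; both must be sampled.
#' @return Growth rate (1/d).
#' @examples
#' growthRate(c(1e6, 2e6), times = c(0, 24), t0 = 0, t1 = 24)  # ln 2
#' @export
growthRate <- function(values, times, t0, t1) {
  if (t0 >= t1) stop("need t0 < t1")
  i0 <- which(abs(times - t0) < 1e-8)
  i1 <- which(abs(times - t1) < 1e-8)
  if (length(i0) != 1 || length(i1) != 1)
    stop("t0 and t1 must each match exactly one sampling time")
  if (values[i0] <= 0 || values[i1] <= 0)
    stop("abundances must be > 0 for growth-rate estimation")
  log(values[i1] / values[i0]) / (t1 - t0) * 24
}

## one-sample t test of replicate values against 0, robust to zero variance
.oneSampleP <- function(x) {
  if (length(x) < 2) return(NA_real_)
  if (stats::sd(x) == 0) return(if (mean(x) == 0) 1 else 0)
  stats::t.test(x, mu = 0)$p.value
}

#' Latent-period interval from replicate virion fold changes
#'
#' The latent period is bracketed by the sampling interval in which the
#' free-virion log2 fold change first becomes significantly greater than
#' zero: at each post-reference timepoint the replicate log2 fold changes
#' are tested against 0 (two-sided one-sample t test by default, matching
#' the reporting convention; a one-sided option exists since the quantity
#' is directional) and the earliest timepoint with \code{p < alpha}
#' \emph{and} positive mean closes the interval. Detection can never
#' precede the first timepoint with positive mean fold change.
#'
#' @param series data.frame with columns \code{time_h}, \code{replicate}
#'   and \code{value} (virion concentrations).
#' @param referenceTime reference timepoint for the fold change (h).
#' @param alpha significance threshold.
#' @param sided \code{"two"} (default) or \code{"one"}.
#' @return A list with \code{interval} \eqn{(t_{prev}, t_{sig}]} (upper
#'   bound \code{Inf} and \code{detected = FALSE} when no timepoint is
#'   significant), and a per-timepoint \code{table} of means and p values.
#' @examples
#' df <- expand.grid(time_h = c(0.5, 6.5, 8.5), replicate = 1:3)
#' df$value <- 1e7 * 2^(ifelse(df$time_h > 7, 2, 0) + rnorm(9, 0, 0.01))
#' latentPeriod(df)$interval
#' @export
latentPeriod <- function(series, referenceTime = 0.5, alpha = 0.05,
                         sided = c("two", "one")) {
  sided <- match.arg(sided)
  stopifnot(all(c("time_h", "replicate", "value") %in% names(series)))
  series <- series[series$time_h >= referenceTime - 1e-8, ]
  reps <- split(series, series$replicate)
  if (length(reps) < 2) stop("need >= 2 replicates per timepoint")
  lfc <- do.call(rbind, lapply(reps, function(df) {
    df <- df[order(df$time_h), ]
    df$log2fc <- log2FoldChange(df$value, reference = referenceTime,
                                times = df$time_h)
    df
  }))
  tps <- sort(unique(lfc$time_h))
  post <- tps[tps > referenceTime + 1e-8]
  tab <- do.call(rbind, lapply(post, function(tp) {
    x <- lfc$log2fc[abs(lfc$time_h - tp) < 1e-8]
    p <- .oneSampleP(x)
    if (sided == "one" && !is.na(p))
      p <- if (mean(x) > 0) p / 2 else 1 - p / 2
    data.frame(time_h = tp, mean_log2fc = mean(x), p_value = p)
  }))
  sig <- which(!is.na(tab$p_value) & tab$p_value < alpha &
                 tab$mean_log2fc > 0)
  if (length(sig)) {
    j <- sig[1]
    prev <- if (j == 1) referenceTime else tab$time_h[j - 1]
    list(interval = c(prev, tab$time_h[j]), detected = TRUE, table = tab)
  } else {
    list(interval = c(max(tps), Inf), detected = FALSE, table = tab)
  }
}

#' Burst size from late-infection virion gain and host loss
#'
#' Per replicate, \eqn{b = (V(t_2) - V(t_1)) / (H(t_1) - H(t_2))} over a
#' late-infection window (default 18.5-24.5 h, the convention for this
#' experimental design; configurable because the appropriate window is
#' where host lysis actually occurs). Replicates with host gain over the
#' window have no defined burst size and are excluded with a warning.
#' The estimator is invariant to the concentration unit as long as both
#' series share it.
#'
#' @param virusSeries,hostSeries data.frames with columns \code{time_h},
#'   \code{replicate}, \code{value}, sampled at both window endpoints.
#' @param window numeric length-2 window (h).
#' @return List with \code{mean}, \code{sd}, per-replicate estimates
#'   \code{perReplicate}, and indices of \code{excluded} replicates.
#' @examples
#' v <- data.frame(time_h = rep(c(18.5, 24.5), 3),
#'                 replicate = rep(1:3, each = 2),
#'                 value = rep(c(1e8, 2e8), 3))
#' h <- data.frame(time_h = rep(c(18.5, 24.5), 3),
#'                 replicate = rep(1:3, each = 2),
#'                 value = rep(c(2e6, 1e6), 3))
#' burstSize(v, h)$mean  # 100
#' @export
burstSize <- function(virusSeries, hostSeries, window = c(18.5, 24.5)) {
  pick <- function(df, tp, r)
    df$value[abs(df$time_h - tp) < 1e-8 & df$replicate == r]
  reps <- sort(unique(virusSeries$replicate))
  b <- vapply(reps, function(r) {
    v1 <- pick(virusSeries, window[1], r); v2 <- pick(virusSeries, window[2], r)
    h1 <- pick(hostSeries, window[1], r);  h2 <- pick(hostSeries, window[2], r)
    if (!all(lengths(list(v1, v2, h1, h2)) == 1))
      stop("series must be sampled at both window endpoints per replicate")
    loss <- h1 - h2
    if (loss <= 0) return(NA_real_)
    (v2 - v1) / loss
  }, numeric(1))
  excluded <- which(is.na(b))
  if (length(excluded))
    warning("replicate(s) ", paste(reps[excluded], collapse = ", "),
            " gained hosts over the window; burst size undefined, excluded")
  ok <- b[!is.na(b)]
  list(mean = if (length(ok)) mean(ok) else NA_real_,
       sd = if (length(ok) > 1) stats::sd(ok) else NA_real_,
       perReplicate = stats::setNames(b, reps), excluded = reps[excluded],
       window = window)
}

#' Viral production as fold change in virion abundance
#'
#' \eqn{VP = N_t / N_i} per replicate and timepoint, with the
#' first post-inoculation sample as reference. Identical to
#' \eqn{2^{n_t}} for the log2 fold change \eqn{n_t}.
#'
#' @param series data.frame with columns \code{time_h}, \code{replicate},
#'   \code{value}.
#' @param referenceTime reference timepoint (h).
#' @return The input with a \code{vp} column appended.
#' @export
viralProduction <- function(series, referenceTime = 0.5) {
  reps <- split(series, series$replicate)
  out <- do.call(rbind, lapply(reps, function(df) {
    df <- df[order(df$time_h), ]
    j <- which(abs(df$time_h - referenceTime) < 1e-8)
    if (length(j) != 1) stop("reference time not sampled")
    if (df$value[j] <= 0) stop("reference abundance must be > 0")
    df$vp <- df$value / df$value[j]
    df
  }))
  rownames(out) <- NULL
  out
}

#' Light-sensitivity ratio of viral production
#'
#' Per timepoint after the release of progeny virions, the ratio of mean
#' viral production under limited vs standard light,
#' \eqn{VP_{LL} / VP_{SL}}; a ratio of 1 means production is insensitive to
#' host growth condition. Replicate flasks are independent across light
#' conditions, so the standard error follows first-order error propagation
#' of the two means, and the group contrast is a Welch two-sample t test.
#'
#' @param vpLL,vpSL data.frames from [viralProduction()] for the two light
#'   conditions.
#' @param afterH only timepoints strictly later than this enter (default
#'   8.5 h, the first interval after progeny release).
#' @return data.frame per timepoint: ratio, propagated SE, Welch p value.
#' @export
sensitivityRatio <- function(vpLL, vpSL, afterH = 8.5) {
  tps <- sort(intersect(unique(vpLL$time_h), unique(vpSL$time_h)))
  tps <- tps[tps >= afterH - 1e-8]
  out <- lapply(tps, function(tp) {
    a <- vpLL$vp[abs(vpLL$time_h - tp) < 1e-8]
    b <- vpSL$vp[abs(vpSL$time_h - tp) < 1e-8]
    mb <- mean(b)
    if (mb <= 0) {
      return(data.frame(time_h = tp, ratio = NA_real_, se = NA_real_,
                        p_welch = NA_real_))
    }
    r <- mean(a) / mb
    se <- r * sqrt(stats::var(a) / length(a) / mean(a)^2 +
                     stats::var(b) / length(b) / mb^2)
    p <- tryCatch(stats::t.test(a, b)$p.value, error = function(e) NA_real_)
    data.frame(time_h = tp, ratio = r, se = se, p_welch = p)
  })
  do.call(rbind, out)
}

#' Per-timepoint statistical-testing protocol
#'
#' At each timepoint: one-way ANOVA across treatment levels with Type II
#' sums of squares (identical to Type I in this balanced one-way layout,
#' but stated explicitly), Tukey-adjusted pairwise comparisons, and Welch
#' two-sample t tests for every pair (the unequal-variance contrasts used
#' for two-group questions). P values are reported per timepoint without
#' multiplicity correction across timepoints; set \code{holm = TRUE} to
#' apply a Holm correction to the ANOVA p values.
#'
#' Timepoints where every group has zero within-group variance are
#' degenerate (no error stratum): their p values are \code{NA} and they
#' are flagged.
#'
#' @param data data.frame with columns \code{time_h}, \code{treatment},
#'   \code{replicate}, \code{value}; >= 2 treatments with >= 2 replicates.
#' @param alpha significance threshold recorded in the output.
#' @param holm correct ANOVA p values across timepoints (off by default).
#' @return List of data.frames: \code{anova} (per timepoint F, p,
#'   degeneracy flag), \code{tukey} (per timepoint and pair: difference,
#'   interval, adjusted p), \code{welch} (per timepoint and pair: t, df,
#'   p).
#' @export
testProtocol <- function(data, alpha = 0.05, holm = FALSE) {
  stopifnot(all(c("time_h", "treatment", "value") %in% names(data)))
  data$treatment <- factor(data$treatment)
  if (nlevels(data$treatment) < 2) stop("need >= 2 treatment groups")
  tps <- sort(unique(data$time_h))
  anovaL <- list(); tukeyL <- list(); welchL <- list()
  for (tp in tps) {
    d <- data[abs(data$time_h - tp) < 1e-8, ]
    d$treatment <- droplevels(d$treatment)
    if (min(table(d$treatment)) < 2) stop("need >= 2 replicates per group")
    degenerate <- all(tapply(d$value, d$treatment, stats::sd) == 0)
    if (degenerate) {
      anovaL[[length(anovaL) + 1L]] <-
        data.frame(time_h = tp, F = NA_real_, p_value = NA_real_,
                   degenerate = TRUE)
    } else {
      fit <- stats::lm(value ~ treatment, data = d)
      a2 <- car::Anova(fit, type = 2)
      anovaL[[length(anovaL) + 1L]] <-
        data.frame(time_h = tp, F = a2$`F value`[1],
                   p_value = a2$`Pr(>F)`[1], degenerate = FALSE)
      tk <- stats::TukeyHSD(stats::aov(value ~ treatment, data = d))$treatment
      tukeyL[[length(tukeyL) + 1L]] <-
        data.frame(time_h = tp, contrast = rownames(tk),
                   diff = tk[, "diff"], lwr = tk[, "lwr"],
                   upr = tk[, "upr"], p_adj = tk[, "p adj"],
                   row.names = NULL)
    }
    prs <- utils::combn(levels(d$treatment), 2)
    welchL[[length(welchL) + 1L]] <- do.call(rbind, lapply(
      seq_len(ncol(prs)), function(k) {
        x <- d$value[d$treatment == prs[1, k]]
        y <- d$value[d$treatment == prs[2, k]]
        tt <- tryCatch(stats::t.test(x, y), error = function(e) NULL)
        data.frame(time_h = tp,
                   contrast = paste(prs[2, k], prs[1, k], sep = "-"),
                   t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
                   df = if (is.null(tt)) NA_real_ else unname(tt$parameter),
                   p_value = if (is.null(tt)) NA_real_ else tt$p.value)
      }))
  }
  an <- do.call(rbind, anovaL)
  if (holm) an$p_value <- stats::p.adjust(an$p_value, "holm")
  list(anova = an,
       tukey = if (length(tukeyL)) do.call(rbind, tukeyL) else NULL,
       welch = do.call(rbind, welchL), alpha = alpha)
}
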