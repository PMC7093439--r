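# Statistical workflow: mixed-design repeated-measures ANOVA, gated
# per-timepoint t-tests, and the preparation-characteristics table.

#' Mixed-design repeated-measures ANOVA
#'
#' Two-way ANOVA with one between-subjects factor (group) and one
#' within-subjects factor (time): the classic split-plot decomposition, in
#' which the group effect is tested against the between-subject stratum
#' and time and the group-by-time interaction against the within-subject
#' stratum.  Requires every subject to be measured at every time (no
#' imputation).  A Greenhouse-Geisser sphericity correction for the
#' within-subject tests is available behind `gg`; it is off by default.
#'
#' @param df Long data frame.
#' @param value,group,time,subject Column names in `df`.
#' @param gg Apply the Greenhouse-Geisser correction to the within-subject
#'   p-values.
#' @return Tibble with columns `effect` ("group", "time", "group:time"),
#'   `df1`, `df2`, `F`, `p` (and `gg_epsilon` when `gg = TRUE`).
#' @export
rm_anova <- function(df, value = "pct_of_stab", group = "arm",
                     time = "time_min", subject = "prep_id", gg = FALSE) {
  d <- data.frame(y = df[[value]], g = factor(df[[group]]),
                  t = factor(df[[time]]), s = factor(df[[subject]]))
  if (anyNA(d)) stop("missing values in ANOVA input; no imputation", call. = FALSE)
  tab <- table(d$s, d$t)
  if (any(tab != 1))
    stop("unbalanced design: every subject must appear exactly once per time",
         call. = FALSE)
  if (min(table(unique(d[c("s", "g")])$g)) < 2)
    stop("need at least two subjects per group", call. = FALSE)
  fit <- stats::aov(y ~ g * t + Error(s), data = d)
  sm <- summary(fit)
  between <- sm[["Error: s"]][[1]]
  within <- sm[["Error: Within"]][[1]]
  pick <- function(stratum, label) {
    i <- grep(label, trimws(rownames(stratum)), fixed = TRUE)[1]
    r <- grep("Residuals", trimws(rownames(stratum)))[1]
    tibble::tibble(df1 = stratum$Df[i], df2 = stratum$Df[r],
                   F = stratum$`F value`[i], p = stratum$`Pr(>F)`[i])
  }
  out <- dplyr::bind_rows(
    dplyr::mutate(pick(between, "g"), effect = "group"),
    dplyr::mutate(pick(within, "t"), effect = "time"),
    dplyr::mutate(pick(within, "g:t"), effect = "group:time"))
  out <- out[, c("effect", "df1", "df2", "F", "p")]
  if (gg) {
    eps <- gg_epsilon(d)
    wi <- out$effect != "group"
    out$p[wi] <- stats::pf(out$F[wi], eps * out$df1[wi], eps * out$df2[wi],
                           lower.tail = FALSE)
    out$gg_epsilon <- ifelse(wi, eps, NA_real_)
  }
  out
}

# Greenhouse-Geisser epsilon from the pooled within-group covariance of
# the repeated measures.
gg_epsilon <- function(d) {
  wide <- stats::reshape(d[, c("s", "t", "y")], idvar = "s", timevar = "t",
                         direction = "wide")
  g_of_s <- d$g[!duplicated(d$s)][match(wide$s, unique(d$s))]
  y <- as.matrix(wide[, -1])
  centred <- do.call(rbind, lapply(split(as.data.frame(y), g_of_s), function(m)
    scale(as.matrix(m), center = TRUE, scale = FALSE)))
  S <- stats::cov(centred)
  k <- ncol(S)
  C <- diag(k) - 1 / k
  St <- C %*% S %*% C
  eps <- sum(diag(St))^2 / ((k - 1) * sum(St^2))
  max(1 / (k - 1), min(1, eps))
}

#' Per-timepoint independent-samples t-tests
#'
#' Two-sided, pooled-variance (equal-variance) t-tests of drug vs vehicle
#' at each requested time.  No multiple-testing correction is applied
#' across time points; the caller gates these tests on a significant
#' repeated-measures ANOVA.
#'
#' @param drug,vehicle Long data frames with `time_min` and the value
#'   column.
#' @param times_min Times at which to test.
#' @param value Value column name.
#' @return Tibble with `time_min`, `t`, `df`, `p`.
#' @export
per_timepoint_ttests <- function(drug, vehicle, times_min,
                                 value = "pct_of_stab") {
  rows <- lapply(times_min, function(tm) {
    x <- drug[[value]][drug$time_min == tm]
    y <- vehicle[[value]][vehicle$time_min == tm]
    if (length(x) < 2 || length(y) < 2)
      stop("need at least two preparations per group for a t-test", call. = FALSE)
    df <- length(x) + length(y) - 2
    if (stats::var(x) + stats::var(y) == 0) {
      # degenerate (noise-free) samples: no within-group variance
      d <- mean(x) - mean(y)
      tibble::tibble(time_min = tm, t = ifelse(d == 0, 0, sign(d) * Inf),
                     df = df, p = as.numeric(d == 0))
    } else {
      ht <- stats::t.test(x, y, var.equal = TRUE)
      tibble::tibble(time_min = tm, t = unname(ht$statistic),
                     df = unname(ht$parameter), p = ht$p.value)
    }
  })
  dplyr::bind_rows(rows)
}

#' Preparation characteristics of a study dataset
#'
#' Assembles the per-preparation anatomy and baseline-performance table
#' (length of maximal force, twitch forces, cross-sectional area, stress,
#' mass and end-of-stabilisation net power) for one or more simulated
#' datasets, labelled by treatment group.
#'
#' @param ... One or more `wl_study_data` objects.
#' @return Tibble, one row per preparation.
#' @export
prep_characteristics <- function(...) {
  datasets <- list(...)
  rows <- lapply(datasets, function(data) {
    stab_end <- data$config$schedule$stabilisation_end_min
    dplyr::bind_rows(lapply(c(data$drug, data$vehicle), function(p) {
      tibble::tibble(
        group = p$treatment, prep_id = p$prep_id,
        L_max_mm = p$params$L_opt,
        F_active_mN = p$twitch$F_active_mN,
        F_passive_mN = p$twitch$F_passive_mN,
        F_developed_mN = p$twitch$F_developed_mN,
        CSA_m2 = p$geometry$CSA_m2,
        stress_kN_m2 = p$geometry$stress_kN_m2,
        mass_ug = p$params$mass * 1e9,
        P_end_stab_W_per_kg =
          p$metrics$Pnorm_W_per_kg[p$metrics$time_min == stab_end])
    }))
  })
  dplyr::distinct(dplyr::bind_rows(rows), .data$prep_id, .keep_all = TRUE)
}

#' Group comparison of preparation characteristics
#'
#' For each characteristic: group mean and SD, a one-way ANOVA p-value
#' across groups, and Bonferroni-adjusted pairwise t-test p-values
#' (`p_adj = min(1, m * p_raw)` with `m` the number of group pairs).
#'
#' @param chars Tibble from [prep_characteristics()] (column `group` plus
#'   numeric characteristic columns).
#' @return List with `summary` (group mean +/- SD per characteristic),
#'   `anova` (one-way ANOVA per characteristic) and `pairwise`
#'   (Bonferroni-adjusted pairwise p-values).
#' @export
characteristics_table <- function(chars) {
  grp <- factor(chars$group)
  if (nlevels(grp) < 2) stop("need at least two groups", call. = FALSE)
  vars <- setdiff(names(chars), c("group", "prep_id"))
  vars <- vars[vapply(chars[vars], is.numeric, TRUE)]
  m_pairs <- choose(nlevels(grp), 2)

  summary <- dplyr::bind_rows(lapply(vars, function(v) {
    dplyr::summarise(chars, characteristic = v, mean = mean(.data[[v]]),
                     sd = stats::sd(.data[[v]]), n = dplyr::n(),
                     .by = "group")
  }))

  anova <- dplyr::bind_rows(lapply(vars, function(v) {
    fit <- stats::aov(chars[[v]] ~ grp)
    s <- summary(fit)[[1]]
    tibble::tibble(characteristic = v, F = s$`F value`[1], p = s$`Pr(>F)`[1])
  }))

  pairs <- utils::combn(levels(grp), 2, simplify = FALSE)
  pairwise <- dplyr::bind_rows(lapply(vars, function(v) {
    dplyr::bind_rows(lapply(pairs, function(pr) {
      x <- chars[[v]][grp == pr[1]]
      y <- chars[[v]][grp == pr[2]]
      p_raw <- stats::t.test(x, y, var.equal = TRUE)$p.value
      tibble::tibble(characteristic = v, group1 = pr[1], group2 = pr[2],
                     p_raw = p_raw, p_bonferroni = min(1, m_pairs * p_raw))
    }))
  }))

  list(summary = summary, anova = anova, pairwise = pairwise)
}
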