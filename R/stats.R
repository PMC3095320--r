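# Promoter comparison statistics: one-way ANOVA, Tukey HSD (Tukey-Kramer
# for unequal n) with a compact letter display, Low/Moderate/High
# classification against the reference promoter, variance partition between
# primary events and clonal secondary roots, and intensity ~ copy-number
# regression. ANOVA, Tukey p-values and OLS come from the stats package;
# the letter assignment (insert-and-absorb) and the classification rule are
# implemented here.

#' Coerce to an intensity table
#'
#' @param x a named list of numeric vectors (one per promoter) or a
#'   data.frame with columns `promoter`/`group` and
#'   `corrected_mean`/`value`/`intensity`.
#' @return a named list of numeric vectors (class `intensity_table`).
#' @export
as_intensity_table <- function(x) {
  if (inherits(x, "intensity_table")) return(x)
  if (is.data.frame(x)) {
    gcol <- intersect(c("promoter", "promoter_id", "group"), names(x))[1]
    vcol <- intersect(c("corrected_mean", "value", "intensity"), names(x))[1]
    if (is.na(gcol) || is.na(vcol))
      stop("data.frame needs a group and a value column", call. = FALSE)
    x <- split(x[[vcol]], x[[gcol]])
  }
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("groups must be named", call. = FALSE)
  structure(lapply(x, as.numeric), class = "intensity_table")
}

table_long <- function(tbl) {
  data.frame(
    group = factor(rep(names(tbl), lengths(tbl)), levels = names(tbl)),
    value = unlist(tbl, use.names = FALSE))
}

#' One-way ANOVA across promoters
#'
#' Classical between/within decomposition; `F = MS_between / MS_within`.
#' When every residual is zero (all groups constant) the result is flagged
#' `degenerate` with `F = Inf` (or `NaN` if there is no between-group
#' spread either).
#'
#' @param tbl an intensity table (see [as_intensity_table()]).
#' @return list of class `anova_result`: `F`, `df_between`, `df_within`,
#'   `p`, `ms_within`, `degenerate`.
#' @export
one_way_anova <- function(tbl) {
  tbl <- as_intensity_table(tbl)
  if (length(tbl) < 2) stop("need at least two groups", call. = FALSE)
  d <- table_long(tbl)
  if (nrow(d) <= length(tbl))
    stop("total N must exceed the number of groups", call. = FALSE)
  a <- suppressWarnings(stats::anova(stats::lm(value ~ group, data = d)))
  msw <- a["Residuals", "Mean Sq"]
  degenerate <- msw < .Machine$double.eps * max(1, mean(d$value)^2)
  Fv <- if (degenerate) {
    if (a["group", "Mean Sq"] > 0) Inf else NaN
  } else a["group", "F value"]
  p <- if (degenerate) {
    if (is.infinite(Fv)) 0 else NaN
  } else a["group", "Pr(>F)"]
  structure(list(F = Fv, df_between = a["group", "Df"],
                 df_within = a["Residuals", "Df"], p = p,
                 ms_within = msw, degenerate = degenerate),
            class = "anova_result")
}

# All pairwise Tukey-Kramer adjusted p-values (matrix, groups x groups).
tukey_p_matrix <- function(tbl) {
  d <- table_long(tbl)
  fit <- stats::aov(value ~ group, data = d)
  tk <- stats::TukeyHSD(fit)$group
  k <- length(tbl)
  pm <- matrix(NA_real_, k, k, dimnames = list(names(tbl), names(tbl)))
  diag(pm) <- 1
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  for (i in seq_along(pairs)) {
    a <- pairs[[i]][1]; b <- pairs[[i]][2]
    pm[a, b] <- pm[b, a] <- tk[i, "p adj"]
  }
  pm
}

# Insert-and-absorb compact letter display. `sig` is a logical matrix of
# pairwise significance; `ordered` gives the group order for lettering
# (conventionally by decreasing mean).
cld_insert_absorb <- function(sig, ordered) {
  cols <- list(ordered)
  for (i in seq_along(ordered)) {
    for (j in seq_along(ordered)) {
      if (j <= i) next
      a <- ordered[i]; b <- ordered[j]
      if (!isTRUE(sig[a, b])) next
      hit <- vapply(cols, function(cc) a %in% cc && b %in% cc, TRUE)
      if (!any(hit)) next
      new_cols <- list()
      for (ci in seq_along(cols)) {
        cc <- cols[[ci]]
        if (hit[ci]) {
          new_cols <- c(new_cols, list(setdiff(cc, a)), list(setdiff(cc, b)))
        } else new_cols <- c(new_cols, list(cc))
      }
      # absorb: drop columns that are subsets of another column
      keep <- rep(TRUE, length(new_cols))
      for (ci in seq_along(new_cols)) {
        for (cj in seq_along(new_cols)) {
          if (ci == cj || !keep[ci]) next
          if (all(new_cols[[ci]] %in% new_cols[[cj]]) &&
              (length(new_cols[[ci]]) < length(new_cols[[cj]]) || ci > cj)) {
            keep[ci] <- FALSE
          }
        }
      }
      cols <- new_cols[keep]
    }
  }
  cols <- cols[lengths(cols) > 0]
  # order columns by the best-ranked member so 'a' sits on the top group
  first_rank <- vapply(cols, function(cc) min(match(cc, ordered)), 1)
  cols <- cols[order(first_rank)]
  lab <- c(letters, paste0(rep(letters, each = 26), letters))
  out <- stats::setNames(rep("", length(ordered)), ordered)
  for (ci in seq_along(cols))
    for (g in cols[[ci]]) out[g] <- paste0(out[g], lab[ci])
  out
}

#' Tukey HSD compact letter display
#'
#' All pairwise comparisons use the studentized range with the
#' Tukey-Kramer unequal-n adjustment; letters are assigned by the
#' insert-and-absorb algorithm so two promoters share a letter exactly when
#' their comparison is non-significant at `alpha`.
#'
#' @param tbl an intensity table.
#' @param alpha familywise significance level, default 0.05.
#' @return list of class `tukey_grouping`: `letters` (named character,
#'   ordered by decreasing mean), `alpha`, `p_matrix`.
#' @export
tukey_letters <- function(tbl, alpha = 0.05) {
  tbl <- as_intensity_table(tbl)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0,1)", call. = FALSE)
  if (length(tbl) == 1) {
    return(structure(list(letters = stats::setNames("a", names(tbl)),
                          alpha = alpha, p_matrix = NULL),
                     class = "tukey_grouping"))
  }
  means <- vapply(tbl, mean, numeric(1))
  ordered <- names(sort(means, decreasing = TRUE))
  pm <- tukey_p_matrix(tbl)
  sig <- pm < alpha
  sig[is.na(sig)] <- FALSE
  lets <- cld_insert_absorb(sig, ordered)
  structure(list(letters = lets[ordered], alpha = alpha, p_matrix = pm),
            class = "tukey_grouping")
}

#' Decode a letter display back into a sharing matrix
#'
#' @param letters named character vector of letter sets.
#' @return logical matrix: `TRUE` when two groups share at least one letter.
#' @export
letters_share_matrix <- function(letters) {
  k <- length(letters)
  sets <- lapply(strsplit(letters, ""), unique)
  out <- matrix(TRUE, k, k, dimnames = list(names(letters), names(letters)))
  for (i in seq_len(k))
    for (j in seq_len(k))
      out[i, j] <- length(intersect(sets[[i]], sets[[j]])) > 0
  out
}

#' Classify promoter strength against the reference
#'
#' A promoter is `High` when its mean exceeds the reference mean and it
#' shares no Tukey letter with the reference; `Low` when its mean is below
#' the reference mean and it shares no letter; `Moderate` otherwise.
#'
#' @param tbl an intensity table containing `reference_label`.
#' @param grouping a [tukey_letters()] result for the same table.
#' @param reference_label reference promoter (e.g. `"CaMV35S"`).
#' @return data.frame (class `strength_class`) with columns
#'   `promoter, n, mean, sd, letters, fold_vs_reference, class`.
#' @export
classify_strength <- function(tbl, grouping, reference_label = "CaMV35S") {
  tbl <- as_intensity_table(tbl)
  if (!reference_label %in% names(tbl))
    stop("reference promoter '", reference_label, "' not in the table",
         call. = FALSE)
  lets <- grouping$letters
  share <- letters_share_matrix(lets)
  means <- vapply(tbl, mean, numeric(1))
  refm <- means[[reference_label]]
  cls <- vapply(names(tbl), function(g) {
    if (g == reference_label) return("Moderate")
    shared <- share[g, reference_label]
    if (!shared && means[[g]] > refm) "High"
    else if (!shared && means[[g]] < refm) "Low"
    else "Moderate"
  }, "")
  out <- data.frame(promoter = names(tbl), n = lengths(tbl),
                    mean = unname(means),
                    sd = vapply(tbl, stats::sd, numeric(1)),
                    letters = unname(lets[names(tbl)]),
                    fold_vs_reference = unname(means) / refm,
                    class = unname(cls))
  rownames(out) <- NULL
  class(out) <- c("strength_class", class(out))
  out
}

#' Variation among primary events versus within secondary roots
#'
#' Hairy-root events are independent transformation events, so intensity
#' varies strongly among them; secondary roots are clonal outgrowths of one
#' event and should vary far less.
#'
#' @param secondary named list: for each primary event, the intensities of
#'   its secondary roots (>= 2 events with >= 2 roots each for a defined
#'   ratio).
#' @return list: `between_sd` (SD among event means), `within_sd` (mean
#'   within-event SD), `ratio` (`between/within`, `NaN` when undefined) and
#'   `undefined` flag.
#' @export
within_vs_between_variation <- function(secondary) {
  if (length(secondary) < 2)
    stop("need at least two primary events", call. = FALSE)
  ev_means <- vapply(secondary, mean, numeric(1))
  ev_sds <- vapply(secondary, function(v) {
    if (length(v) < 2) NA_real_ else stats::sd(v)
  }, numeric(1))
  between <- stats::sd(ev_means)
  within <- mean(ev_sds, na.rm = TRUE)
  undefined <- !is.finite(within) || within == 0
  list(between_sd = between, within_sd = within,
       ratio = if (undefined) NaN else between / within,
       undefined = undefined)
}

#' Regress intensity on transgene copy number
#'
#' Ordinary least squares with a two-sided slope test. Perfectly collinear
#' data give `r_squared = 1` and `p = 0`.
#'
#' @param data data.frame with columns `copy_count` and `intensity`
#'   (>= 3 rows, >= 2 distinct copy counts).
#' @return list of class `regression_result`: `slope`, `intercept`,
#'   `r_squared`, `p`, `n`.
#' @export
fit_regression <- function(data) {
  if (nrow(data) < 3) stop("need at least 3 points", call. = FALSE)
  if (length(unique(data$copy_count)) < 2)
    stop("need at least 2 distinct copy counts", call. = FALSE)
  fit <- stats::lm(intensity ~ copy_count, data = data)
  res <- stats::residuals(fit)
  sst <- sum((data$intensity - mean(data$intensity))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(res^2) / sst
  perfect <- sum(res^2) <= .Machine$double.eps * max(1, sst)
  if (perfect) {
    p <- 0
  } else {
    p <- summary(fit)$coefficients["copy_count", "Pr(>|t|)"]
  }
  structure(list(slope = unname(stats::coef(fit)["copy_count"]),
                 intercept = unname(stats::coef(fit)["(Intercept)"]),
                 r_squared = r2, p = p, n = nrow(data)),
            class = "regression_result")
}

#' Cohort positivity rate
#'
#' Percentage of screened primary roots that express the reporter.
#'
#' @param n_positive,n_negative counts of GFP-positive and -negative roots.
#' @return list: `percent_positive`, `n_total`, `n_positive`, `n_negative`.
#' @export
positivity_rate <- function(n_positive, n_negative) {
  if (n_positive < 0 || n_negative < 0 || n_positive + n_negative == 0)
    stop("counts must be non-negative with a positive total", call. = FALSE)
  total <- n_positive + n_negative
  list(percent_positive = 100 * n_positive / total, n_total = total,
       n_positive = n_positive, n_negative = n_negative)
}
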