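#' One-way ANOVA F statistic on window-level AUCs
#'
#' Treats the per-window AUC values of each group as observations of a
#' one-way layout.  Because overlapping windows are not independent, the F
#' value is descriptive; inference comes from subject-level permutation
#' (see [compare_groups()]), which preserves the window dependence structure
#' under the null.
#'
#' @param auc_by_group list of numeric vectors, one per group (each of
#'   length >= 2).
#' @return the F statistic (possibly `Inf` when the within-group variance is
#'   zero but group means differ).
#' @export
anova_auc <- function(auc_by_group) {
  fail_if(length(auc_by_group) < 2, "need at least two groups")
  sizes <- lengths(auc_by_group)
  fail_if(any(sizes < 2), "insufficient data: every group needs >= 2 windows")
  mats <- lapply(auc_by_group, function(v) matrix(as.numeric(v), nrow = 1))
  as.numeric(fstat_rows(mats))
}

#' Pooled two-sample t statistic
#'
#' Student t with pooled variance and first-minus-second sign convention, so
#' a negative value means the first group is lower.
#'
#' @param a,b numeric vectors (length >= 2 each).
#' @return the t statistic (`Inf`/`-Inf` flagged when the pooled variance is
#'   zero but means differ; 0 when both are constant and equal).
#' @export
posthoc_t <- function(a, b) {
  fail_if(length(a) < 2 || length(b) < 2, "need >= 2 values per group")
  as.numeric(tstat_rows(matrix(as.numeric(a), 1), matrix(as.numeric(b), 1)))
}

# row-wise one-way F over a list of [cells x n_g] matrices
fstat_rows <- function(mats) {
  k <- length(mats)
  ns <- vapply(mats, ncol, integer(1))
  n_tot <- sum(ns)
  means <- vapply(mats, rowMeans, numeric(nrow(mats[[1]])))
  means <- matrix(means, ncol = k)
  gm <- as.vector(means %*% ns) / n_tot
  ssb <- rowSums(sweep((means - gm)^2, 2, ns, `*`))
  ssw <- Reduce(`+`, lapply(seq_len(k), function(g)
    rowSums((mats[[g]] - means[, g])^2)))
  f <- (ssb / (k - 1)) / (ssw / (n_tot - k))
  ok <- !is.na(ssw) & !is.na(ssb)
  f[ok & ssw == 0 & ssb > 0] <- Inf
  f[ok & ssw == 0 & ssb == 0] <- 0
  f[!ok] <- NA_real_
  f
}

# row-wise pooled t between two [cells x n] matrices (first minus second)
tstat_rows <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  tt <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
  zero <- !is.na(sp2) & sp2 == 0
  tt[zero & ma != mb] <- sign(ma - mb)[zero & ma != mb] * Inf
  tt[zero & ma == mb] <- 0
  tt[is.na(sp2)] <- NA_real_
  tt
}

#' Permutation p-value with the add-one rule
#'
#' `p = (1 + #\{|stat_perm| >= |stat_obs|\}) / (n_perm + 1)`; the observed
#' labeling is excluded from the null draws but counted through the added
#' one, so `p` can never be 0 and lies in `[1/(n_perm+1), 1]`.
#'
#' @param obs observed statistic.
#' @param perms vector of permuted statistics.
#' @return permutation p-value.
#' @examples
#' perm_pvalue(5, runif(99))   # 1/100 when obs exceeds all 99 draws
#' @export
perm_pvalue <- function(obs, perms) {
  if (!length(perms)) stop("n_perm must be >= 1", call. = FALSE)
  if (is.na(obs)) return(NA_real_)
  (1 + sum(abs(perms) >= abs(obs), na.rm = TRUE)) / (length(perms) + 1)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values, monotone in rank, applied within one family of
#' tests.
#'
#' @param p vector of p-values in `[0, 1]` (NAs passed through).
#' @return q-values of the same length.
#' @export
fdr_correct <- function(p) {
  fail_if(any(p < 0 | p > 1, na.rm = TRUE), "p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

# flatten a cohort_aucs object into per-group [cells x windows] matrices plus
# a cell annotation table
auc_cells <- function(aucs) {
  groups <- aucs$groups
  g1 <- groups[1]
  cells <- data.frame(metric = character(0), node = character(0))
  per_group <- lapply(groups, function(g) NULL)
  names(per_group) <- groups
  blocks <- list()
  glob_metrics <- colnames(aucs$global[[g1]])
  if (length(glob_metrics) > 0) {
    cells <- rbind(cells, data.frame(metric = glob_metrics, node = "global"))
    blocks$global <- TRUE
  }
  nodal_metrics <- names(aucs$nodal[[g1]])
  for (mn in nodal_metrics) {
    nodes <- colnames(aucs$nodal[[g1]][[mn]])
    cells <- rbind(cells, data.frame(metric = mn, node = nodes))
  }
  mats <- lapply(groups, function(g) {
    glob <- t(aucs$global[[g]])                  # metrics x windows
    nod <- lapply(nodal_metrics, function(mn) t(aucs$nodal[[g]][[mn]]))
    do.call(rbind, c(list(glob), nod))
  })
  names(mats) <- groups
  list(cells = cells, mats = mats)
}

# all statistics (F + pairwise t) for one labeled cohort
cohort_statistics <- function(cohort, config, seed, regions) {
  aucs <- cohort_aucs(cohort, config, seed = seed, regions = regions)
  ac <- auc_cells(aucs)
  groups <- aucs$groups
  pairs <- utils::combn(groups, 2)
  stats <- list()
  if (length(groups) >= 2) stats[["F"]] <- fstat_rows(ac$mats)
  for (p in seq_len(ncol(pairs))) {
    lab <- sprintf("%s vs %s", pairs[1, p], pairs[2, p])
    stats[[lab]] <- tstat_rows(ac$mats[[pairs[1, p]]], ac$mats[[pairs[2, p]]])
  }
  list(cells = ac$cells, stats = do.call(cbind, stats),
       window_counts = aucs$window_counts,
       disconnected = aucs$disconnected)
}

#' Permutation-based group comparison of metric AUCs
#'
#' The headline inference engine.  For the observed cohort it computes, for
#' every metric cell (each global metric, and each node of each nodal
#' metric), a one-way F statistic plus pooled-t post-hoc contrasts on the
#' window-level AUCs.  Subject group labels are then permuted `n_perm` times
#' preserving group sizes; the entire window/SCN/metric/AUC pipeline is
#' re-run on each relabeling and two-sided permutation p-values are obtained
#' with the add-one rule.  Benjamini-Hochberg FDR correction is applied
#' within families: the 68 nodes of each nodal metric form one family per
#' statistic, and the global metrics together form one family per statistic.
#'
#' @param cohort thickness table with >= 2 groups.
#' @param config an [scn_config()]; `config$n_perm` is the default
#'   permutation count.
#' @param n_perm number of permutations (>= 1).
#' @param seed master seed; the identical statistic sub-seed is used for the
#'   observed and every permuted cohort so the statistic is a fixed function
#'   of the labeled data.
#' @param regions region labels defining node order.
#' @return a data.frame of class `"scn_comparison"` with columns `metric`,
#'   `node`, `contrast` (`"F"` or `"<a> vs <b>"`), `statistic`, `p_perm`,
#'   `q_fdr` and `direction` (sign of a t contrast, `NA` for F).
#' @export
compare_groups <- function(cohort, config = scn_config(),
                           n_perm = config$n_perm, seed = config$seed,
                           regions = dk_atlas()$label) {
  fail_if(n_perm < 1, "n_perm: must be >= 1, got %d", n_perm)
  groups <- if (is.factor(cohort$group)) levels(droplevels(cohort$group))
            else unique(as.character(cohort$group))
  fail_if(length(groups) < 2, "need at least two groups")
  # fix group order so cells and contrasts align between observed and
  # permuted pipelines
  cohort$group <- factor(cohort$group, levels = groups)
  stat_seed <- derive_seed(seed, "statistics")
  obs <- cohort_statistics(cohort, config, stat_seed, regions)
  exceed <- matrix(0, nrow(obs$stats), ncol(obs$stats))
  withr::with_seed(derive_seed(seed, "permutation"), {
    for (b in seq_len(n_perm)) {
      perm <- cohort
      perm$group <- sample(cohort$group)
      pst <- cohort_statistics(perm, config, stat_seed, regions)
      hit <- abs(pst$stats) >= abs(obs$stats)
      hit[is.na(hit)] <- TRUE   # conservative: an undefined draw never helps
      exceed <- exceed + hit
    }
  })
  pvals <- (1 + exceed) / (n_perm + 1)
  pvals[is.na(obs$stats)] <- NA_real_

  qvals <- pvals
  fam_id <- ifelse(obs$cells$node == "global", "global", obs$cells$metric)
  for (fam in unique(fam_id)) {
    rows <- fam_id == fam
    for (cc in seq_len(ncol(qvals)))
      qvals[rows, cc] <- fdr_correct(pvals[rows, cc])
  }

  res <- do.call(rbind, lapply(seq_len(ncol(obs$stats)), function(cc) {
    contrast <- colnames(obs$stats)[cc]
    data.frame(metric = obs$cells$metric,
               node = obs$cells$node,
               contrast = contrast,
               statistic = obs$stats[, cc],
               p_perm = pvals[, cc],
               q_fdr = qvals[, cc],
               direction = if (contrast == "F") NA_real_
                           else sign(obs$stats[, cc]),
               stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  attr(res, "n_perm") <- n_perm
  attr(res, "window_counts") <- obs$window_counts
  attr(res, "disconnected") <- obs$disconnected
  class(res) <- c("scn_comparison", "data.frame")
  res
}

#' Classify asymptomatic neurocognitive impairment (ANI) from domain T-scores
#'
#' A cognitive domain is mildly impaired when its T-score lies more than one
#' but less than two standard deviations below the normative mean of 50
#' (i.e. in `[30, 40)` on the T scale).  A subject is classified `"ANI"` when
#' at least two domains are mildly impaired and daily functioning is intact.
#' Any domain more than two standard deviations below the mean (`T < 30`) or
#' impaired daily functioning places the subject beyond what this rule can
#' label, returning `"not-classifiable"`; otherwise the subject is
#' `"non-HAND"`.  T-scores are expected to be already adjusted for
#' demographics (the normative adjustment is an input, not done here).
#'
#' @param t_scores numeric vector of six domain T-scores (verbal fluency,
#'   executive function, processing speed, fine motor, attention/working
#'   memory, learning/delayed recall), or a matrix/data.frame with six
#'   columns for several subjects.
#' @param adl_impaired logical: decreased activities of daily living.
#' @return character: `"ANI"`, `"non-HAND"` or `"not-classifiable"`.
#' @examples
#' classify_ani(c(45, 38, 36, 50, 52, 55), adl_impaired = FALSE)   # "ANI"
#' @export
classify_ani <- function(t_scores, adl_impaired) {
  if (is.data.frame(t_scores)) t_scores <- as.matrix(t_scores)
  if (is.matrix(t_scores)) {
    fail_if(ncol(t_scores) != 6, "need exactly six domain T-scores, got %d",
            ncol(t_scores))
    fail_if(length(adl_impaired) != nrow(t_scores),
            "adl_impaired must match the number of subjects")
    return(vapply(seq_len(nrow(t_scores)),
                  function(i) classify_ani(t_scores[i, ], adl_impaired[i]),
                  character(1)))
  }
  fail_if(length(t_scores) != 6, "need exactly six domain T-scores, got %d",
          length(t_scores))
  fail_if(anyNA(t_scores) || any(!is.finite(t_scores)),
          "missing or non-finite domain T-score")
  fail_if(!is.logical(adl_impaired) || length(adl_impaired) != 1 ||
            is.na(adl_impaired), "adl_impaired must be TRUE or FALSE")
  if (any(t_scores < 30) || adl_impaired) return("not-classifiable")
  n_mild <- sum(t_scores >= 30 & t_scores < 40)
  if (n_mild >= 2) "ANI" else "non-HAND"
}
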