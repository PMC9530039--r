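#' Specify a synthetic multi-group thickness cohort
#'
#' Defines a factor-model generator for regional cortical thickness: each
#' subject draws one latent factor per community plus one global factor, and
#' the thickness of region \eqn{r} in a subject of group \eqn{g} is
#' \deqn{x_r = \mu_r + \beta (age - \bar a) + s\,(w_g F_{m(r)} + c_g G + \epsilon_r \sigma)}
#' with standard-normal \eqn{F_m}, \eqn{G} and \eqn{\epsilon_r}.  The loads
#' `within_module_load` (\eqn{w_g}), `cross_module_load` (\eqn{c_g}) and
#' `noise_sd` (\eqn{\sigma}) are dimensionless and fully determine the
#' interregional correlation structure: two regions in the same community
#' correlate at \eqn{(w_g^2 + c_g^2)/(w_g^2 + c_g^2 + \sigma^2)}, two regions
#' in different communities at \eqn{c_g^2/(w_g^2 + c_g^2 + \sigma^2)}.  The
#' morphometric scale `morpho_scale` (\eqn{s}, in mm) sets the across-subject
#' thickness variability without touching correlations, keeping simulated
#' thickness strictly positive and on a realistic mm scale.
#'
#' Defaults emulate a three-group adult cohort (sizes 34/31/35, ages 25-50)
#' with six lobe-like covariance communities and a mild age-related thinning
#' trend.
#'
#' @param group_names labels of the groups.
#' @param group_sizes positive integers, one per group.
#' @param age_range numeric `c(min, max)` in years, min < max.
#' @param region_count number of atlas regions (68).
#' @param module_assignment named integer vector mapping region labels to
#'   community indices; default [atlas_communities()].
#' @param baseline_mean mean thickness in mm, length 1 or `region_count`.
#' @param within_module_load per-group loading of the community factor,
#'   recycled across groups; must satisfy `within^2 + cross^2 < 1`... the
#'   loads are free up to that implied-correlation validity bound.
#' @param cross_module_load per-group loading of the global factor.
#' @param age_slope mm/year thinning coefficient (negative = thinning).
#' @param noise_sd residual load (> 0), dimensionless.
#' @param morpho_scale mm scale converting the latent variation into
#'   thickness variability.
#' @param prop_male probability a simulated subject is male.
#' @param seed integer RNG seed; the same seed always yields the identical
#'   table.
#' @return an object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(group_names = c("cARTpos", "cARTneg", "HC"),
                        group_sizes = c(34L, 31L, 35L),
                        age_range = c(25, 50),
                        region_count = 68L,
                        module_assignment = atlas_communities(),
                        baseline_mean = 2.5,
                        within_module_load = 0.7,
                        cross_module_load = 0.2,
                        age_slope = -0.01,
                        noise_sd = 0.4,
                        morpho_scale = 0.15,
                        prop_male = 0.94,
                        seed = 1L) {
  spec <- list(group_names = as.character(group_names),
               group_sizes = as.integer(group_sizes),
               age_range = as.numeric(age_range),
               region_count = as.integer(region_count),
               module_assignment = module_assignment,
               baseline_mean = baseline_mean,
               within_module_load = rep_len(within_module_load, length(group_names)),
               cross_module_load = rep_len(cross_module_load, length(group_names)),
               age_slope = age_slope,
               noise_sd = noise_sd,
               morpho_scale = morpho_scale,
               prop_male = prop_male,
               seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  validate_spec(spec)
  spec
}

validate_spec <- function(spec) {
  fail_if(length(spec$group_names) < 1 ||
            length(spec$group_sizes) != length(spec$group_names),
          "group_sizes: must supply one size per group name")
  fail_if(anyDuplicated(spec$group_names) > 0, "group_names: labels must be unique")
  fail_if(any(spec$group_sizes < 1L), "group_sizes: all sizes must be >= 1")
  fail_if(length(spec$age_range) != 2 || spec$age_range[1] >= spec$age_range[2],
          "age_range: need [min, max] with min < max")
  fail_if(spec$region_count < 2L, "region_count: must be >= 2")
  fail_if(length(spec$module_assignment) != spec$region_count,
          "module_assignment: need one community per region (%d)", spec$region_count)
  fail_if(!length(spec$baseline_mean) %in% c(1L, spec$region_count),
          "baseline_mean: length 1 or region_count")
  fail_if(any(spec$baseline_mean <= 0), "baseline_mean: thickness must be positive")
  fail_if(spec$noise_sd <= 0, "noise_sd: must be > 0")
  fail_if(spec$morpho_scale <= 0, "morpho_scale: must be > 0")
  fail_if(any(spec$within_module_load < 0) || any(spec$within_module_load >= 1),
          "within_module_load: must lie in [0, 1)")
  fail_if(any(spec$cross_module_load < 0) || any(spec$cross_module_load >= 1),
          "cross_module_load: must lie in [0, 1)")
  fail_if(any(spec$within_module_load^2 + spec$cross_module_load^2 >= 1),
          "within_module_load: within^2 + cross^2 must be < 1")
  fail_if(spec$prop_male < 0 || spec$prop_male > 1, "prop_male: must be in [0, 1]")
  fail_if(is.na(spec$seed), "seed: must be an integer")
  invisible(spec)
}

#' Generate a synthetic thickness cohort
#'
#' Draws one row per subject across all groups of a [cohort_spec()].  Ages
#' are uniform in `age_range`, rounded to 0.1 year; subject identifiers embed
#' the group so that age ties break deterministically.  Output is
#' bit-identical under a fixed seed.
#'
#' @param spec a [cohort_spec()].
#' @return a data.frame of class `"scn_cohort"` with columns `subject_id`,
#'   `group`, `age`, `sex` and one thickness column per region label.
#' @examples
#' cohort <- generate_cohort(cohort_spec(seed = 7))
#' dim(cohort)   # 100 subjects x (4 + 68) columns
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  validate_spec(spec)
  regions <- names(spec$module_assignment)
  if (is.null(regions)) regions <- paste0("R", seq_len(spec$region_count))
  n_mod <- max(spec$module_assignment)
  mid_age <- mean(spec$age_range)
  baseline <- rep_len(spec$baseline_mean, spec$region_count)

  withr::with_seed(spec$seed, {
    rows <- vector("list", length(spec$group_names))
    for (g in seq_along(spec$group_names)) {
      n <- spec$group_sizes[g]
      ages <- round(runif(n, spec$age_range[1], spec$age_range[2]), 1)
      sexes <- ifelse(runif(n) < spec$prop_male, "M", "F")
      f_mod <- matrix(rnorm(n * n_mod), n, n_mod)   # per-subject community factors
      f_glob <- rnorm(n)                            # per-subject global factor
      eps <- matrix(rnorm(n * spec$region_count), n, spec$region_count)
      latent <- spec$within_module_load[g] * f_mod[, spec$module_assignment, drop = FALSE] +
        spec$cross_module_load[g] * f_glob +
        spec$noise_sd * eps
      thick <- matrix(baseline, n, spec$region_count, byrow = TRUE) +
        spec$age_slope * (ages - mid_age) +
        spec$morpho_scale * latent
      colnames(thick) <- regions
      grp_tag <- gsub("[^A-Za-z0-9]", "", spec$group_names[g])
      rows[[g]] <- data.frame(
        subject_id = sprintf("%s_%03d", grp_tag, seq_len(n)),
        group = spec$group_names[g],
        age = ages,
        sex = sexes,
        thick,
        check.names = FALSE,
        stringsAsFactors = FALSE
      )
    }
  })
  cohort <- do.call(rbind, rows)
  rownames(cohort) <- NULL
  # group order is part of the design: fix it so downstream contrasts do not
  # depend on row order
  cohort$group <- factor(cohort$group, levels = spec$group_names)
  class(cohort) <- c("scn_cohort", "data.frame")
  cohort
}

#' Validate a thickness table
#'
#' Checks a cohort table against the input contract: unique subject ids, the
#' full set of 68 region columns, strictly positive thickness, numeric ages,
#' a group label per row.  All problems are collected (not fail-fast) and
#' returned as a character vector, each naming the offending row/column.
#'
#' @param table a data.frame as produced by [generate_cohort()] or
#'   [read_cohort()].
#' @param regions expected region labels; default the DK registry.
#' @return character vector of error messages (length 0 when valid).
#' @export
validate_cohort <- function(table, regions = dk_atlas()$label) {
  errors <- character(0)
  need <- c("subject_id", "group", "age", "sex")
  miss <- setdiff(need, names(table))
  if (length(miss) > 0)
    errors <- c(errors, sprintf("missing metadata column '%s'", miss))
  miss_reg <- setdiff(regions, names(table))
  if (length(miss_reg) > 0)
    errors <- c(errors, sprintf("missing region column '%s'", miss_reg))
  if ("subject_id" %in% names(table)) {
    dup <- unique(table$subject_id[duplicated(table$subject_id)])
    if (length(dup) > 0)
      errors <- c(errors, sprintf("duplicate subject_id '%s'", dup))
  }
  if ("age" %in% names(table) && (!is.numeric(table$age) || anyNA(table$age)))
    errors <- c(errors, "column 'age' must be numeric and complete")
  present <- intersect(regions, names(table))
  for (r in present) {
    v <- table[[r]]
    if (!is.numeric(v)) {
      errors <- c(errors, sprintf("region column '%s' is not numeric", r))
      next
    }
    bad <- which(is.na(v) | v <= 0)
    if (length(bad) > 0)
      errors <- c(errors,
                  sprintf("non-positive or missing thickness at row %d, column '%s'",
                          bad, r))
  }
  errors
}

assert_cohort <- function(table, regions = dk_atlas()$label) {
  errs <- validate_cohort(table, regions)
  fail_if(length(errs) > 0, "invalid thickness table:\n%s",
          paste("-", errs, collapse = "\n"))
  invisible(table)
}

#' Write / read a thickness cohort as TSV
#'
#' Plain UTF-8 tab-separated text with a mandatory header
#' `subject_id group age sex <region columns>` and `.` as decimal separator.
#'
#' @param table cohort data.frame.
#' @param path file path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns a
#'   validated `"scn_cohort"` data.frame.
#' @export
write_cohort <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  fail_if(!file.exists(path), "file not found: %s", path)
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  assert_cohort(tab)
  class(tab) <- c("scn_cohort", "data.frame")
  tab
}
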