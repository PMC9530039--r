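#' Desikan-Killiany region registry
#'
#' The 68 gyrus-based cortical parcels (34 per hemisphere) that define the
#' nodes of every structural covariance network in this package.  Each region
#' carries an abbreviation (the node label used in all outputs, e.g.
#' `"SFG.L"`), its full anatomical name, hemisphere, and a fixed assignment
#' to one of six lobe-like communities (frontal, parietal, temporal,
#' occipital, cingulate, paracentral/insular).  The community column is the
#' default module assignment of the synthetic cohort generator; it is a fixed
#' documentation choice, not an empirical parcellation of covariance.
#'
#' @return A data.frame with 68 rows and columns `index` (1..68), `label`
#'   (abbreviation plus hemisphere suffix, e.g. `"SFG.L"`), `abbrev`, `name`,
#'   `hemisphere` (`"L"`/`"R"`) and `community`.
#' @examples
#' atlas <- dk_atlas()
#' nrow(atlas)                      # 68
#' table(atlas$hemisphere)          # 34 L, 34 R
#' @export
dk_atlas <- function() {
  base <- data.frame(
    abbrev = c("BSTS", "cACG", "cMFG", "CUN", "ENT", "FUS", "IPG", "ITG",
               "iCG", "LOG", "lOFC", "LING", "mOFC", "MTG", "PHG", "PCL",
               "pOPER", "pORB", "pTRI", "CAL", "PoCG", "PCG", "PreCG",
               "PCUN", "ACG", "rMFG", "SFG", "SPG", "STG", "SMG", "FP",
               "TP", "TTG", "INS"),
    name = c("banks of the superior temporal sulcus",
             "caudal anterior cingulate gyrus",
             "caudal middle frontal gyrus",
             "cuneus",
             "entorhinal cortex",
             "fusiform gyrus",
             "inferior parietal gyrus",
             "inferior temporal gyrus",
             "isthmus of the cingulate gyrus",
             "lateral occipital gyrus",
             "lateral orbitofrontal cortex",
             "lingual gyrus",
             "medial orbitofrontal cortex",
             "middle temporal gyrus",
             "parahippocampal gyrus",
             "paracentral lobule",
             "pars opercularis",
             "pars orbitalis",
             "pars triangularis",
             "pericalcarine cortex",
             "postcentral gyrus",
             "posterior cingulate gyrus",
             "precentral gyrus",
             "precuneus",
             "rostral anterior cingulate gyrus",
             "rostral middle frontal gyrus",
             "superior frontal gyrus",
             "superior parietal gyrus",
             "superior temporal gyrus",
             "supramarginal gyrus",
             "frontal pole",
             "temporal pole",
             "transverse temporal gyrus",
             "insula"),
    community = c("temporal", "cingulate", "frontal", "occipital", "temporal",
                  "temporal", "parietal", "temporal", "cingulate", "occipital",
                  "frontal", "occipital", "frontal", "temporal", "temporal",
                  "paracentral", "frontal", "frontal", "frontal", "occipital",
                  "parietal", "cingulate", "frontal", "parietal", "cingulate",
                  "frontal", "frontal", "parietal", "temporal", "parietal",
                  "frontal", "temporal", "temporal", "paracentral"),
    stringsAsFactors = FALSE
  )
  atlas <- rbind(
    transform(base, hemisphere = "L", label = paste0(abbrev, ".L")),
    transform(base, hemisphere = "R", label = paste0(abbrev, ".R"))
  )
  atlas$index <- seq_len(nrow(atlas))
  rownames(atlas) <- atlas$label
  atlas[, c("index", "label", "abbrev", "name", "hemisphere", "community")]
}

#' Look up a region by label
#'
#' @param label region label such as `"SFG.L"`.
#' @param atlas a registry as returned by [dk_atlas()].
#' @return the one-row data.frame for that region.
#' @examples
#' atlas_lookup("SFG.L")$name   # "superior frontal gyrus"
#' @export
atlas_lookup <- function(label, atlas = dk_atlas()) {
  fail_if(!label %in% atlas$label, "unknown region label '%s'", label)
  atlas[atlas$label == label, , drop = FALSE]
}

#' Default module assignment for the synthetic generator
#'
#' @param atlas a registry as returned by [dk_atlas()].
#' @return named integer vector mapping each of the 68 region labels to one
#'   of six community indices.
#' @export
atlas_communities <- function(atlas = dk_atlas()) {
  comm <- as.integer(factor(atlas$community,
                            levels = c("frontal", "parietal", "temporal",
                                       "occipital", "cingulate", "paracentral")))
  names(comm) <- atlas$label
  comm
}
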