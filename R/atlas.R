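#' Canonical 42-tract white-matter atlas table
#'
#' The fixture list of the 42 major white-matter fiber bundles whose FA and
#' MD are tabulated per subject (the standard whole-brain autosegmentation
#' set: 19 bilateral bundles plus four midline structures). Tract identifiers
#' are used as cohort-table column stems (`<tract>_FA`, `<tract>_MD`).
#'
#' @return A data frame with 42 rows: `tract` (unique identifier, e.g.
#'   `"SLF III_R"`), `hemisphere` (`"L"`, `"R"` or `"M"`), `display_name`,
#'   and `group` (association / projection / commissural / limbic).
#' @export
tract_atlas <- function() {
  pairs <- list(
    c("AF",      "arcuate fasciculus",                  "association"),
    c("AR",      "acoustic radiation",                  "projection"),
    c("ATR",     "anterior thalamic radiation",         "projection"),
    c("CBD",     "cingulum bundle, dorsal",             "limbic"),
    c("CBP",     "cingulum bundle, peri-genual",        "limbic"),
    c("CBT",     "cingulum bundle, temporal",           "limbic"),
    c("CST",     "corticospinal tract",                 "projection"),
    c("FA",      "frontal aslant tract",                "association"),
    c("FX",      "fornix",                              "limbic"),
    c("IFO",     "inferior fronto-occipital fasciculus", "association"),
    c("ILF",     "inferior longitudinal fasciculus",    "association"),
    c("MDLF",    "middle longitudinal fasciculus",      "association"),
    c("OR",      "optic radiation",                     "projection"),
    c("SLF I",   "superior longitudinal fasciculus I",  "association"),
    c("SLF II",  "superior longitudinal fasciculus II", "association"),
    c("SLF III", "superior longitudinal fasciculus III", "association"),
    c("STR",     "superior thalamic radiation",         "projection"),
    c("UF",      "uncinate fasciculus",                 "association"),
    c("VOF",     "vertical occipital fasciculus",       "association")
  )
  singles <- list(
    c("FMA", "forceps major",             "commissural"),
    c("FMI", "forceps minor",             "commissural"),
    c("MCP", "middle cerebellar peduncle", "commissural"),
    c("AC",  "anterior commissure",       "commissural")
  )
  rows <- list()
  for (p in pairs) for (h in c("L", "R")) {
    rows[[length(rows) + 1L]] <- data.frame(
      tract = paste0(p[1], "_", h), hemisphere = h,
      display_name = paste(p[2], if (h == "L") "(left)" else "(right)"),
      group = p[3], stringsAsFactors = FALSE)
  }
  for (s in singles) {
    rows[[length(rows) + 1L]] <- data.frame(
      tract = s[1], hemisphere = "M", display_name = s[2], group = s[3],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Default planted tract-effect template
#'
#' Standardized CD-vs-HC shifts for each of the 42 tracts: 25 tracts carry a
#' negative FA shift and 40 carry a positive MD shift (the middle cerebellar
#' peduncle and anterior commissure are spared on MD), mirroring the spatial
#' pattern of widespread white-matter involvement with relative sparing of
#' commissural/cerebellar midline structures. The default magnitude of 0.8
#' standard deviations is a strong but realistic group effect for chronic
#' hypercortisolism.
#'
#' @param fa_magnitude absolute standardized FA decrease for affected tracts.
#' @param md_magnitude absolute standardized MD increase for affected tracts.
#' @return A data frame with `tract`, `fa_shift`, `md_shift` (42 rows).
#' @export
default_tract_effects <- function(fa_magnitude = 0.8, md_magnitude = 0.8) {
  atlas <- tract_atlas()
  fa_hit <- c("AF_L", "AF_R", "ATR_L", "ATR_R", "CBD_L", "CBD_R",
              "CST_L", "CST_R", "FMA", "FMI", "FX_L", "FX_R",
              "IFO_L", "IFO_R", "ILF_L", "ILF_R",
              "SLF I_L", "SLF I_R", "SLF II_L", "SLF II_R",
              "SLF III_L", "SLF III_R", "UF_L", "UF_R", "STR_L")
  md_spared <- c("MCP", "AC")
  stopifnot(all(fa_hit %in% atlas$tract), length(fa_hit) == 25L)
  data.frame(
    tract = atlas$tract,
    fa_shift = ifelse(atlas$tract %in% fa_hit, -abs(fa_magnitude), 0),
    md_shift = ifelse(atlas$tract %in% md_spared, 0, abs(md_magnitude)),
    stringsAsFactors = FALSE
  )
}

#' Default per-tract baseline means
#'
#' Deterministic, spatially varied healthy-control baselines: FA between
#' about 0.32 and 0.53, MD between about 0.68 and 0.80 (10^-3 mm^2/s),
#' assigned by a fixed cycling rule so every tract has a distinct but
#' reproducible baseline.
#'
#' @return A data frame with `tract`, `fa_mean`, `md_mean` (MD in
#'   10^-3 mm^2/s).
#' @export
default_tract_baselines <- function() {
  atlas <- tract_atlas()
  i <- seq_len(nrow(atlas))
  data.frame(
    tract = atlas$tract,
    fa_mean = 0.32 + 0.21 * ((i * 7L) %% 13L) / 13,
    md_mean = 0.68 + 0.12 * ((i * 5L) %% 11L) / 11,
    stringsAsFactors = FALSE
  )
}
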