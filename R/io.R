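#' Read a DWI dataset from NIfTI + FSL-style gradient files
#'
#' Loads a 4-D NIfTI volume, its `.bval`/`.bvec` text files and a brain
#' mask, enforcing the dataset invariants: matching volume counts, at least
#' one b = 0 volume, at least six distinct diffusion directions, and unit
#' gradient norms on the b > 0 shell (renormalised when the deviation is
#' below 1e-3, rejected beyond). The bvec dialect (3 x n rows vs n x 3) is
#' auto-detected. Volumes whose stored orientation is not RAS are reoriented
#' through the NIfTI affine; an undecodable orientation is an error.
#'
#' @param nifti_path path to the 4-D DWI NIfTI (.nii or .nii.gz).
#' @param bval_path path to the whitespace-delimited b-value file.
#' @param bvec_path path to the gradient-direction file.
#' @param mask_path path to a 3-D mask NIfTI; `NULL` means all voxels.
#' @return A `dwi_dataset`.
#' @export
read_dwi <- function(nifti_path, bval_path, bvec_path, mask_path = NULL) {
  for (p in c(nifti_path, bval_path, bvec_path, mask_path))
    if (!file.exists(p)) abort("file not found: %s", p)
  img <- RNifti::readNifti(nifti_path)
  if (RNifti::orientation(img) != "RAS") {
    old <- RNifti::orientation(img)
    RNifti::orientation(img) <- "RAS"
    message(sprintf("reoriented DWI volume from %s to RAS", old))
  }
  signals <- unclass(img)[, , , , drop = FALSE]
  if (length(dim(signals)) != 4L) abort("DWI NIfTI must be 4-D")
  bvals <- scan(bval_path, quiet = TRUE)
  bv <- as.matrix(utils::read.table(bvec_path))
  if (nrow(bv) == 3L && ncol(bv) != 3L) {
    bv <- t(bv)
    message("bvec file read as 3 x n and transposed")
  } else if (ncol(bv) != 3L) {
    abort("bvec file must be 3 x n or n x 3")
  }
  if (!any(bvals == 0)) abort("no b = 0 volume present")
  nz <- bvals > 0
  nrm <- sqrt(rowSums(bv^2))
  if (any(abs(nrm[nz] - 1) > 1e-3))
    abort("non-unit bvecs beyond tolerance on the b > 0 shell")
  bv[nz, ] <- bv[nz, , drop = FALSE] / nrm[nz]
  mask <- if (is.null(mask_path)) array(TRUE, dim(signals)[1:3])
          else unclass(RNifti::readNifti(mask_path)) > 0
  if (!all(dim(mask) == dim(signals)[1:3]))
    abort("mask dimensions do not match the DWI volume")
  vx <- RNifti::pixdim(img)[1:3]
  dwi <- structure(list(signals = array(as.numeric(signals), dim(signals)),
                        bvals = bvals, bvecs = unname(bv),
                        mask = array(as.logical(mask), dim(mask)),
                        voxel_size_mm = vx, orientation = "RAS"),
                   class = "dwi_dataset")
  validate_dwi(dwi)
  dwi
}

#' Write a DWI dataset as NIfTI + bval/bvec (FSL layout)
#'
#' @param dwi a `dwi_dataset`.
#' @param nifti_path,bval_path,bvec_path,mask_path output paths; the bvec
#'   file is written in the FSL 3 x n orientation.
#' @return Invisibly, the NIfTI path.
#' @export
write_dwi <- function(dwi, nifti_path, bval_path, bvec_path, mask_path = NULL) {
  stopifnot(inherits(dwi, "dwi_dataset"))
  img <- RNifti::asNifti(dwi$signals)
  RNifti::pixdim(img) <- c(dwi$voxel_size_mm, 1)
  RNifti::writeNifti(img, nifti_path)
  writeLines(paste(format(dwi$bvals, scientific = FALSE, trim = TRUE),
                   collapse = " "), bval_path)
  utils::write.table(t(dwi$bvecs), bvec_path, row.names = FALSE,
                     col.names = FALSE)
  if (!is.null(mask_path))
    RNifti::writeNifti(RNifti::asNifti(array(as.numeric(dwi$mask), dim(dwi$mask))),
                       mask_path)
  invisible(nifti_path)
}

# Required non-tract cohort columns, in schema order.
cohort_base_columns <- function() {
  c("subject_id", "group", "age", "sex", "ed", "bmi", "tbv",
    "cortisol_8am", "cortisol_4pm", "cortisol_0000", "alps")
}

#' Write a cohort table to CSV
#'
#' Numeric cells are rendered with 17 significant digits so that a
#' write/read round trip reproduces every double bit-exactly; missing
#' 4 p.m./00:00 cortisol for controls becomes an empty cell.
#'
#' @param cohort cohort data frame.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort
  for (nm in names(out)) {
    if (is.numeric(out[[nm]])) {
      v <- sprintf("%.17g", out[[nm]])
      v[is.na(out[[nm]])] <- ""
      out[[nm]] <- v
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' Validates the schema: all base columns present, every tract-metric column
#' named `<tract>_FA` / `<tract>_MD` for a canonical atlas tract, unique
#' subject ids, groups restricted to CD/HC. Empty cortisol cells are read as
#' missing; a control row carrying 00:00 cortisol triggers a warning since
#' controls are not sampled at night.
#'
#' @param path CSV path.
#' @return The typed cohort data frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) abort("file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  base <- cohort_base_columns()
  missing <- setdiff(base, names(df))
  if (length(missing))
    abort("cohort file lacks required column(s): %s", paste(missing, collapse = ", "))
  extra <- setdiff(names(df), base)
  atlas <- tract_atlas()
  valid_tract_cols <- c(paste0(atlas$tract, "_FA"), paste0(atlas$tract, "_MD"))
  unknown <- setdiff(extra, valid_tract_cols)
  if (length(unknown))
    abort("unknown tract column(s): %s", paste(unknown, collapse = ", "))
  if (anyDuplicated(df$subject_id))
    abort("duplicated subject_id: %s",
          paste(unique(df$subject_id[duplicated(df$subject_id)]), collapse = ", "))
  if (!all(df$group %in% c("CD", "HC"))) abort("group must be CD or HC")
  for (nm in setdiff(names(df), c("subject_id", "group", "sex")))
    df[[nm]] <- as.numeric(df[[nm]])
  if (any(df$group == "HC" & !is.na(df$cortisol_0000)))
    warning("HC row(s) carry 00:00 cortisol; controls are not sampled at night",
            call. = FALSE)
  df
}

#' Assemble a full-run configuration
#'
#' Bundles the stage configurations and the per-section covariate sets used
#' by [run_full_analysis()]. `mode` selects which synthetic inputs are
#' generated: `"phantom"` (imaging arm only), `"cohort"` (statistics arm
#' only) or `"full"` (both). When `cohort_path` is given the table is read
#' from disk instead of simulated.
#'
#' @param mode `"full"`, `"phantom"` or `"cohort"`.
#' @param phantom a [phantom_config()].
#' @param cohort a [cohort_config()].
#' @param cohort_path optional CSV path of a precomputed cohort (must carry
#'   an `alps` column).
#' @param covariates_comparison adjustment set for the ALPS/tract group
#'   comparisons.
#' @param covariates_alps_tract adjustment set for the ALPS-tract
#'   correlation panel (adds the three cortisol time points).
#' @param covariates_cortisol adjustment set for the cortisol-ALPS
#'   correlations.
#' @param fdr_alpha FDR threshold for significance flags.
#' @param mediation a [mediation_spec()].
#' @param rater_subjects,rater_max_shift phantom-arm rater-agreement study
#'   size and ROI jitter.
#' @param seed master seed; stage sub-seeds derive from it.
#' @return An object of class `run_config`.
#' @export
run_config <- function(mode = c("full", "phantom", "cohort"),
                       phantom = phantom_config(),
                       cohort = cohort_config(),
                       cohort_path = NULL,
                       covariates_comparison = c("age", "sex", "ed", "bmi", "tbv"),
                       covariates_alps_tract = c("age", "sex", "ed", "bmi", "tbv",
                                                 "cortisol_0000", "cortisol_8am",
                                                 "cortisol_4pm"),
                       covariates_cortisol = c("age", "sex", "ed", "bmi", "tbv"),
                       fdr_alpha = 0.05,
                       mediation = mediation_spec(),
                       rater_subjects = 12L, rater_max_shift = 1L,
                       seed = 1L) {
  mode <- match.arg(mode)
  if (fdr_alpha <= 0 || fdr_alpha >= 1) abort("'fdr_alpha' must be in (0, 1)")
  if (!is.null(cohort_path) && !file.exists(cohort_path))
    abort("cohort_path does not exist: %s", cohort_path)
  structure(list(mode = mode, phantom = phantom, cohort = cohort,
                 cohort_path = cohort_path,
                 covariates_comparison = covariates_comparison,
                 covariates_alps_tract = covariates_alps_tract,
                 covariates_cortisol = covariates_cortisol,
                 fdr_alpha = fdr_alpha, mediation = mediation,
                 rater_subjects = as.integer(rater_subjects),
                 rater_max_shift = as.integer(rater_max_shift),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Scalar fields in the file override the [run_config()] defaults; nested
#' `phantom`, `cohort` and `mediation` blocks override the corresponding
#' constructor arguments.
#'
#' @param path a `.yaml`/`.yml` or `.json` file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort("file not found: %s", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyVector = TRUE)
  args <- list()
  for (blk in c("phantom", "cohort", "mediation")) {
    if (!is.null(raw[[blk]])) {
      ctor <- switch(blk, phantom = phantom_config, cohort = cohort_config,
                     mediation = mediation_spec)
      args[[blk]] <- do.call(ctor, raw[[blk]])
      raw[[blk]] <- NULL
    }
  }
  do.call(run_config, c(raw, args))
}

#' Run the full glymphatic analysis pipeline
#'
#' Strings the stages together on synthetic (or supplied) inputs and writes
#' a report bundle: per-section CSV tables, a machine-readable JSON summary
#' and a plain-text log recording seeds and per-analysis sample sizes.
#' Sections: (imaging arm) phantom generation, tensor fit, ALPS extraction
#' and a two-rater ICC study; (statistics arm) demographics, the
#' covariate-adjusted ALPS group comparison, the FA and MD 42-tract panels
#' with FDR, the CD-only ALPS-tract-FA correlation panel, the CD-only
#' cortisol-ALPS correlations, and the cortisol -> ALPS -> SLF III_R FA
#' mediation model. CD-only analyses restrict to rows with the needed
#' cortisol values present; dropped-row counts are logged, never imputed.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed); `NULL` writes
#'   nothing and just returns the report.
#' @return Invisibly, a list of class `analysis_report` with the per-section
#'   results and the `summary` list mirrored into JSON.
#' @export
run_full_analysis <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  log <- c(sprintf("glymphalps run: mode=%s master_seed=%d", config$mode, config$seed))
  report <- list()
  summary <- list(mode = config$mode, seed = config$seed)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      abort("[stage %s] %s (partial outputs above this stage are incomplete)",
            name, conditionMessage(e)))
  }

  if (config$mode %in% c("phantom", "full")) {
    report$phantom <- stage("phantom", {
      cfg <- config$phantom
      cfg$seed <- substream_seed(config$seed, "phantom")
      ph <- generate_dwi_phantom(cfg)
      field <- fit_tensor_loglinear(ph$dwi)
      alps <- alps_from_tensor(field, ph$truth$roi_spec)
      rater <- simulate_rater_study(config$rater_subjects, cfg,
                                    config$rater_max_shift,
                                    seed = substream_seed(config$seed, "raters"))
      list(truth = ph$truth, alps = alps, rater = rater)
    })
    summary$phantom <- list(
      alps_measured = report$phantom$alps$mean_index,
      alps_true = report$phantom$truth$alps_true,
      per_slice = as.list(report$phantom$alps$per_slice_index),
      icc = report$phantom$rater$icc$icc,
      n_rater_subjects = config$rater_subjects)
    log <- c(log, sprintf(
      "phantom: ALPS %.6f (analytic %.6f), rater ICC %.3f over %d subjects",
      summary$phantom$alps_measured, summary$phantom$alps_true,
      summary$phantom$icc, config$rater_subjects))
  }

  if (config$mode %in% c("cohort", "full")) {
    gen <- stage("cohort", {
      if (!is.null(config$cohort_path)) {
        list(cohort = read_cohort(config$cohort_path), truth = NULL)
      } else {
        cfg <- config$cohort
        cfg$seed <- substream_seed(config$seed, "cohort-stage")
        generate_cohort(cfg)
      }
    })
    cohort <- gen$cohort
    cd <- cohort[cohort$group == "CD", , drop = FALSE]
    report$cohort_truth <- gen$truth

    report$demographics <- stage("demographics", demographics_table(cohort))
    alps_cmp <- stage("alps_comparison", {
      r <- adjusted_group_difference(cohort, "alps", config$covariates_comparison)
      r$p_fdr <- fdr_bh(r$p_raw)   # single-test family
      r
    })
    report$alps_comparison <- alps_cmp
    report$tract_fa <- stage("tract_fa", tract_panel_comparison(
      cohort, "FA", config$covariates_comparison, config$fdr_alpha))
    report$tract_md <- stage("tract_md", tract_panel_comparison(
      cohort, "MD", config$covariates_comparison, config$fdr_alpha))
    atlas <- tract_atlas()
    report$alps_tract_corr <- stage("alps_tract_corr", correlation_panel(
      cd, "alps", paste0(atlas$tract, "_FA"),
      config$covariates_alps_tract, config$fdr_alpha))
    report$cortisol_corr <- stage("cortisol_corr", {
      rows <- lapply(c("cortisol_8am", "cortisol_4pm", "cortisol_0000"),
                     function(v) partial_correlation(cd, v, "alps",
                                                     config$covariates_cortisol))
      do.call(rbind, rows)
    })
    med_spec <- config$mediation
    med_spec$seed <- substream_seed(config$seed, "bootstrap")
    report$mediation <- stage("mediation", fit_mediation(cd, med_spec))

    summary$cohort <- list(
      n_cd = sum(cohort$group == "CD"), n_hc = sum(cohort$group == "HC"),
      alps_adjusted_effect = alps_cmp$adjusted_effect,
      alps_p_fdr = alps_cmp$p_fdr,
      fa_tracts_decreased = sum(report$tract_fa$significant &
                                  report$tract_fa$direction == "decrease"),
      md_tracts_increased = sum(report$tract_md$significant &
                                  report$tract_md$direction == "increase"),
      alps_tract_significant = report$alps_tract_corr$y[report$alps_tract_corr$significant],
      cortisol_0000_r = report$cortisol_corr$r[
        report$cortisol_corr$x == "cortisol_0000"],
      mediation = list(acme = report$mediation$acme, ade = report$mediation$ade,
                       te = report$mediation$te,
                       acme_ci = as.numeric(report$mediation$ci["acme", ]),
                       ade_ci = as.numeric(report$mediation$ci["ade", ]),
                       p = as.list(report$mediation$p),
                       classification = report$mediation$classification,
                       n_used = report$mediation$n_used))
    log <- c(log,
      sprintf("cohort: n_cd=%d n_hc=%d", summary$cohort$n_cd, summary$cohort$n_hc),
      sprintf("alps comparison: effect %.4f, FDR p %.4f, n_used %d",
              alps_cmp$adjusted_effect, alps_cmp$p_fdr, alps_cmp$n_used),
      sprintf("tract panels: %d FA-decreased, %d MD-increased (FDR %.2f)",
              summary$cohort$fa_tracts_decreased,
              summary$cohort$md_tracts_increased, config$fdr_alpha),
      sprintf("alps-tract panel: n_used %d (of %d CD); significant: %s",
              report$alps_tract_corr$n[1], nrow(cd),
              paste(summary$cohort$alps_tract_significant, collapse = ", ")),
      sprintf("mediation: ACME %.4f ADE %.4f TE %.4f -> %s (n_used %d, %d degenerate resamples)",
              report$mediation$acme, report$mediation$ade, report$mediation$te,
              report$mediation$classification, report$mediation$n_used,
              report$mediation$n_degenerate))

    if (!is.null(out_dir)) {
      write_cohort(cohort, file.path(out_dir, "cohort.csv"))
      utils::write.csv(report$demographics, file.path(out_dir, "demographics.csv"),
                       row.names = FALSE)
      utils::write.csv(report$tract_fa, file.path(out_dir, "tract_fa_panel.csv"),
                       row.names = FALSE)
      utils::write.csv(report$tract_md, file.path(out_dir, "tract_md_panel.csv"),
                       row.names = FALSE)
      utils::write.csv(report$alps_tract_corr,
                       file.path(out_dir, "alps_tract_correlations.csv"),
                       row.names = FALSE)
      utils::write.csv(report$cortisol_corr,
                       file.path(out_dir, "cortisol_alps_correlations.csv"),
                       row.names = FALSE)
    }
  }

  report$summary <- summary
  report$log <- log
  if (!is.null(out_dir)) {
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(log, file.path(out_dir, "run.log"))
  }
  invisible(structure(report, class = "analysis_report"))
}
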