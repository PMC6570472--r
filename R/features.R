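QUS_PARAMS <- c("MBF", "SS", "SI", "SAS", "ASD", "AAC")
TEXTURES <- c("CON", "COR", "ENE", "HOM")

#' The per-patient QUS feature schema
#'
#' Enumerates the 49 QUS features computed per patient: 13 map means (7
#' core including ACE, 6 margin), 24 core texture features (6 maps x CON /
#' COR / ENE / HOM), 6 core-to-margin ratios and 6 core-to-margin contrast
#' ratios.  Texture is computed on core maps only; the margin contributes
#' means and the contrast denominators.  ACE is a single whole-core scalar
#' (it has no texture or margin entry).  With the three molecular receptor
#' statuses (ER, PR, HER2) the candidate set grows to 52.
#'
#' @param molecular if `TRUE`, append `ER`, `PR`, `HER2`.
#' @return character vector of feature names (49 or 52).
#' @examples
#' length(qus_feature_names())        # 49
#' length(qus_feature_names(TRUE))    # 52
#' @export
qus_feature_names <- function(molecular = FALSE) {
  nm <- c(paste0(c(QUS_PARAMS, "ACE"), "_MEAN_CORE"),
          paste0(QUS_PARAMS, "_MEAN_MARGIN"),
          as.vector(t(outer(QUS_PARAMS, TEXTURES, paste, sep = "_"))),
          paste0(QUS_PARAMS, "_CMR"),
          paste0(QUS_PARAMS, "_CMCR"))
  if (molecular) nm <- c(nm, "ER", "PR", "HER2")
  nm
}

#' Extract the full QUS feature set from one image plane
#'
#' Runs the whole per-plane chain: sliding windows over the core and margin
#' ROIs, reference-normalised spectra per window, the seven parameter
#' estimates, parametric maps, GLCM texture on the core maps, map means,
#' core-to-margin contrast features, and the whole-core attenuation
#' estimate.
#'
#' @param frame an [rf_frame()].
#' @param rois a [build_rois()] result.
#' @param pulse the [make_pulse()] whose analytic spectrum is the
#'   normalisation reference.
#' @param window_mm,overlap window geometry passed to [tile_windows()].
#' @param glcm_levels grey levels for texture quantisation.
#' @param sas_threshold prominence threshold of [estimate_sas()].
#' @param include_ace whether to attempt the attenuation estimate (needs
#'   >= 1 cm of core depth span).
#' @return named numeric vector over [qus_feature_names()]; features that
#'   cannot be computed on this plane are `NA`.
#' @export
extract_plane_features <- function(frame, rois, pulse = make_pulse(),
                                   window_mm = c(2, 2), overlap = 0.94,
                                   glcm_levels = 16L, sas_threshold = 0.32,
                                   include_ace = TRUE) {
  ref <- pulse$reference_psd
  out <- setNames(rep(NA_real_, 49), qus_feature_names())
  maps <- list()
  ace_spectra <- NULL
  for (lab in c("core", "margin")) {
    grid <- tile_windows(rois, frame, roi_label = lab,
                         window_mm = window_mm, overlap = overlap)
    if (!nrow(grid)) next
    est <- matrix(NA_real_, nrow(grid), 6,
                  dimnames = list(NULL, QUS_PARAMS))
    specs_h <- vector("list", nrow(grid))
    for (i in seq_len(nrow(grid))) {
      w <- grid[i, ]
      sp <- normalized_spectrum(frame, w, ref, taper = "hann")
      specs_h[[i]] <- sp
      fitp <- fit_spectral_params(sp)
      ff <- fit_form_factor(sp)
      sr <- normalized_spectrum(frame, w, ref, taper = "rect", nfft = 4096)
      sas <- estimate_sas(sr, prominence_threshold = sas_threshold)
      est[i, ] <- c(fitp$mbf, fitp$ss, fitp$si, sas$sas, ff$asd, ff$aac)
    }
    for (p in QUS_PARAMS)
      maps[[paste(p, lab, sep = ".")]] <- build_map(est[, p], grid, p, lab)
    if (lab == "core") ace_spectra <- specs_h
  }
  if (!length(maps)) return(out)

  for (p in QUS_PARAMS) {
    cm <- maps[[paste(p, "core", sep = ".")]]
    mm <- maps[[paste(p, "margin", sep = ".")]]
    if (!is.null(cm)) {
      cv <- cm$values[is.finite(cm$values)]
      if (length(cv)) out[paste0(p, "_MEAN_CORE")] <- mean(cv)
      tx <- glcm_features(cm, levels = glcm_levels)
      if (!is.null(tx))
        out[paste0(p, "_", TEXTURES)] <- unlist(tx)[c("con", "cor", "ene", "hom")]
    }
    if (!is.null(mm)) {
      mv <- mm$values[is.finite(mm$values)]
      if (length(mv)) out[paste0(p, "_MEAN_MARGIN")] <- mean(mv)
    }
    if (!is.null(cm) && !is.null(mm) &&
        any(is.finite(cm$values)) && any(is.finite(mm$values))) {
      cc <- cmr_cmcr(cm, mm)
      out[paste0(p, "_CMR")] <- cc$cmr %||% NA_real_
      out[paste0(p, "_CMCR")] <- cc$cmcr
    }
  }
  if (include_ace && !is.null(ace_spectra) && length(ace_spectra) >= 3) {
    depths <- vapply(ace_spectra, function(s) s$window_depth_cm, 0)
    if (diff(range(depths)) >= 1)
      out["ACE_MEAN_CORE"] <- estimate_ace(ace_spectra)$ace
  }
  out
}

#' Aggregate per-plane feature vectors into one patient vector
#'
#' Unweighted mean over planes per feature; a feature absent on some planes
#' is averaged over the planes where it is present.  Clinical practice uses
#' 4-7 planes per tumour; fewer are accepted with a warning so that small
#' synthetic studies remain convenient.
#'
#' @param planes list of named numeric vectors from
#'   [extract_plane_features()].
#' @param molecular optional named vector/list with `ER`, `PR`, `HER2`
#'   passed through unchanged.
#' @return named numeric vector (49 QUS features, plus molecular fields if
#'   given).
#' @export
aggregate_patient <- function(planes, molecular = NULL) {
  assert_that(length(planes) >= 1, "need at least one plane")
  if (length(planes) < 4 || length(planes) > 7)
    warning("plane count outside the usual 4-7 range")
  M <- do.call(rbind, lapply(planes, function(p) p[qus_feature_names()]))
  out <- colMeans(M, na.rm = TRUE)
  out[!is.finite(out)] <- NA_real_
  if (any(colSums(is.finite(M)) == 0))
    message("feature(s) absent on all planes: ",
            paste(qus_feature_names()[colSums(is.finite(M)) == 0], collapse = ", "))
  if (!is.null(molecular))
    out <- c(out, unlist(molecular)[c("ER", "PR", "HER2")])
  out
}

#' Write a cohort feature table with its data dictionary
#'
#' One row per patient; missing values as empty cells.  A JSON data
#' dictionary describing each column is written alongside.
#'
#' @param table data.frame of features (and label columns).
#' @param path CSV output path; the dictionary goes to `<path>.dict.json`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "")
  qus <- qus_feature_names()
  dict <- lapply(names(table), function(nm) {
    role <- if (nm %in% qus) "qus_feature"
            else if (nm %in% c("ER", "PR", "HER2")) "molecular_feature"
            else "label"
    list(name = nm, role = role)
  })
  jsonlite::write_json(dict, paste0(path, ".dict.json"), auto_unbox = TRUE)
  invisible(path)
}
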