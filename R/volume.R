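#' Metric-map catalog
#'
#' The 14 per-voxel metric maps: the conventional ADC plus the 13 metrics of
#' the five non-Gaussian models. Diffusivity-like maps (ADC, D, D*, DDC) are
#' reported in 1e-3 mm^2/s (= um^2/ms) to match the usual table units; the
#' FROC spatial constant mu is reported in 1e-3 mm (um); fractions and
#' exponents are dimensionless.
#'
#' @return data.frame with columns `map`, `model`, `param`, `scale`.
#' @export
metric_catalog <- function() {
  data.frame(
    map = c("ADC",
            "IVIM-f", "IVIM-D", "IVIM-Dstar",
            "DKI-K", "DKI-D",
            "SEM-alpha", "SEM-DDC",
            "FROC-beta", "FROC-mu", "FROC-D",
            "CTRW-alpha", "CTRW-beta", "CTRW-D"),
    model = c("ADC", rep("IVIM", 3L), rep("DKI", 2L), rep("SEM", 2L),
              rep("FROC", 3L), rep("CTRW", 3L)),
    param = c("ADC", "f", "D", "Dstar", "K", "D", "alpha", "DDC",
              "beta", "mu", "D", "alpha", "beta", "D"),
    scale = c(1e3, 1, 1e3, 1e3, 1, 1e3, 1, 1e3, 1, 1e3, 1e3, 1, 1, 1e3),
    stringsAsFactors = FALSE)
}

#' Assemble a parameter-map set
#'
#' @param maps named list of 3D arrays on a shared grid; names must be the
#'   14 entries of [metric_catalog()] (or the subset for the fitted models).
#' @param voxel_size numeric length-3, mm per axis.
#' @param qc optional per-model QC list.
#' @param require_full if TRUE, all 14 maps (13 non-ADC) must be present.
#' @return an object of class `param_map_set`.
#' @export
param_map_set <- function(maps, voxel_size = c(1, 1, 1), qc = list(),
                          require_full = TRUE) {
  cat_maps <- metric_catalog()$map
  if (!all(names(maps) %in% cat_maps))
    stop("unknown map name(s): ",
         paste(setdiff(names(maps), cat_maps), collapse = ", "))
  if (require_full && !setequal(names(maps), cat_maps))
    stop("expected all 14 maps; missing: ",
         paste(setdiff(cat_maps, names(maps)), collapse = ", "))
  dims <- lapply(maps, dim)
  if (length(unique(dims)) != 1L)
    stop("all maps must share one grid")
  maps <- maps[intersect(cat_maps, names(maps))]
  structure(list(maps = maps, voxel_size = as.numeric(voxel_size), qc = qc),
            class = "param_map_set")
}

#' @export
print.param_map_set <- function(x, ...) {
  d <- dim(x$maps[[1L]])
  cat("parameter-map set:", length(x$maps), "maps on a",
      paste(d, collapse = "x"), "grid (",
      sum(names(x$maps) != "ADC"), "non-Gaussian metrics )\n")
  invisible(x)
}

#' Fit one model over a masked 4D volume
#'
#' Voxels outside the mask are `NA`; degenerate voxels (non-positive b = 0
#' signal) are fitted to bound-midpoints, flagged, and set `NA` in the
#' emitted maps so they drop out of histogram analysis.
#'
#' @param model model id (see [fit_voxel]).
#' @param dwi 4D array, x-y-z-b.
#' @param mask 3D logical/0-1 array matching `dwi`'s spatial grid.
#' @param scheme a [bval_scheme]; length must match `dim(dwi)[4]`.
#' @param options a [fit_options].
#' @return list with `maps` (named 3D arrays in catalog display units for
#'   this model) and `qc` (`n_voxels`, `frac_converged`, `frac_degenerate`).
#' @export
fit_volume <- function(model, dwi, mask, scheme, options = fit_options()) {
  if (length(dim(dwi)) != 4L) stop("dwi must be a 4D array")
  if (!all(dim(dwi)[1:3] == dim(mask)))
    stop("mask grid ", paste(dim(mask), collapse = "x"),
         " does not match dwi grid ", paste(dim(dwi)[1:3], collapse = "x"))
  if (dim(dwi)[4L] != length(as_b(scheme)))
    stop("dwi has ", dim(dwi)[4L], " volumes but scheme has ",
         length(as_b(scheme)), " b-values")
  cat_rows <- metric_catalog()[metric_catalog()$model == model, ]
  idx <- which(mask > 0)
  shape <- dim(dwi)[1:3]
  maps <- stats::setNames(
    replicate(nrow(cat_rows), array(NA_real_, shape), simplify = FALSE),
    cat_rows$map)
  if (length(idx) == 0L) {
    warning("empty mask: no voxels fitted")
    return(list(maps = maps,
                qc = list(n_voxels = 0L, frac_converged = 0,
                          frac_degenerate = 0)))
  }
  nb <- dim(dwi)[4L]
  flat <- matrix(dwi, ncol = nb)
  conv <- logical(length(idx)); degen <- logical(length(idx))
  for (j in seq_along(idx)) {
    res <- fit_voxel(model, flat[idx[j], ], scheme, options)
    conv[j] <- res$converged; degen[j] <- res$degenerate
    if (!res$degenerate)
      for (r in seq_len(nrow(cat_rows)))
        maps[[r]][idx[j]] <- res$par[[cat_rows$param[r]]] * cat_rows$scale[r]
  }
  list(maps = maps,
       qc = list(n_voxels = length(idx),
                 frac_converged = mean(conv),
                 frac_degenerate = mean(degen)))
}

#' Fit every model and assemble the 14-map set
#'
#' @inheritParams fit_volume
#' @param models character vector of model ids; all six by default.
#' @param voxel_size mm per axis for the emitted map set.
#' @return a [param_map_set] (full when all six models are fitted).
#' @export
fit_all_models <- function(dwi, mask, scheme,
                           models = c("ADC", "IVIM", "DKI", "SEM", "FROC", "CTRW"),
                           options = fit_options(), voxel_size = c(1, 1, 1)) {
  maps <- list(); qc <- list()
  for (m in models) {
    fm <- fit_volume(m, dwi, mask, scheme, options)
    maps <- c(maps, fm$maps)
    qc[[m]] <- fm$qc
    if (fm$qc$n_voxels > 0 && fm$qc$frac_converged < 0.95)
      warning(sprintf("%s: only %.1f%% of voxels converged", m,
                      100 * fm$qc$frac_converged))
  }
  param_map_set(maps, voxel_size = voxel_size, qc = qc,
                require_full = setequal(models,
                                        c("ADC", "IVIM", "DKI", "SEM",
                                          "FROC", "CTRW")))
}
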