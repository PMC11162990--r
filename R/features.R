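#' First-order histogram feature names
#'
#' The 18-feature first-order set extracted from every metric map. The
#' exact list used by the study is in an unavailable appendix; this is the
#' standard IBSI-aligned first-order set (standard deviation omitted as
#' redundant with variance), and it contains every feature named in the
#' study's result tables (mean, median, 10P, 90P, skewness, kurtosis,
#' uniformity, energy, TE).
#'
#' @return character vector of length 18, in canonical column order.
#' @export
first_order_names <- function() {
  c("energy", "TE", "entropy", "min", "10P", "90P", "max", "mean",
    "median", "IQR", "range", "MAD", "rMAD", "RMS", "skewness",
    "kurtosis", "variance", "uniformity")
}

#' Percentile with linear interpolation between closest ranks
#'
#' @param values non-empty numeric vector.
#' @param q percentile in [0, 100].
#' @return interpolated percentile (R quantile type 7 convention).
#' @export
percentile <- function(values, q) {
  if (length(values) == 0L) stop("empty VOI: cannot compute percentile")
  if (q < 0 || q > 100) stop("q must be in [0, 100]")
  unname(stats::quantile(values, q / 100, type = 7, names = FALSE))
}

#' Equal-width discretization into bin probabilities
#'
#' `n_bins` equal-width bins spanning the observed min-max; a constant
#' input occupies a single bin. Used by the entropy and uniformity features;
#' the study does not state its binning, 64 bins is this package's default.
#'
#' @param values non-empty numeric vector.
#' @param n_bins number of bins.
#' @return numeric vector of `n_bins` probabilities summing to 1.
#' @export
discretize <- function(values, n_bins = 64L) {
  if (length(values) == 0L) stop("empty VOI: cannot discretize")
  lo <- min(values); hi <- max(values)
  if (hi == lo) {
    p <- numeric(n_bins); p[1L] <- 1
    return(p)
  }
  width <- (hi - lo) / n_bins
  idx <- pmin(floor((values - lo) / width) + 1L, n_bins)
  tabulate(idx, nbins = n_bins) / length(values)
}

#' Extract the 18 first-order features from a voxel sample
#'
#' Moments are population (biased) moments, the usual radiomics convention;
#' kurtosis is non-excess (a normal distribution gives 3); skewness and
#' kurtosis of a zero-variance sample are defined as 0; entropy is Shannon
#' entropy in bits over the [discretize()] bins.
#'
#' @param values in-VOI metric values (finite, non-empty).
#' @param voxel_volume voxel volume in mm^3 (for total energy).
#' @param n_bins bins for entropy/uniformity.
#' @return named numeric vector of length 18 (see [first_order_names()]).
#' @export
extract_first_order <- function(values, voxel_volume = 1, n_bins = 64L) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n == 0L) stop("empty VOI after removing non-finite voxels")
  mu <- mean(values)
  dev <- values - mu
  m2 <- mean(dev^2); m3 <- mean(dev^3); m4 <- mean(dev^4)
  p <- discretize(values, n_bins)
  pnz <- p[p > 0]
  p10 <- percentile(values, 10); p90 <- percentile(values, 90)
  mid <- values[values >= p10 & values <= p90]
  energy <- sum(values^2)
  c(energy     = energy,
    TE         = voxel_volume * energy,
    entropy    = -sum(pnz * log2(pnz)),
    min        = min(values),
    `10P`      = p10,
    `90P`      = p90,
    max        = max(values),
    mean       = mu,
    median     = stats::median(values),
    IQR        = percentile(values, 75) - percentile(values, 25),
    range      = max(values) - min(values),
    MAD        = mean(abs(dev)),
    rMAD       = if (length(mid)) mean(abs(mid - mean(mid))) else 0,
    RMS        = sqrt(mean(values^2)),
    skewness   = if (m2 > 0) m3 / m2^1.5 else 0,
    kurtosis   = if (m2 > 0) m4 / m2^2 else 0,
    variance   = m2,
    uniformity = sum(p^2))
}

#' Whole-VOI feature vector for one participant
#'
#' 18 features from each of the 14 maps of a [param_map_set], named
#' `<map>-<feature>` (e.g. `CTRW-D-skewness`) -> 252 entries.
#'
#' @param map_set a [param_map_set] with all 14 maps.
#' @param mask 3D VOI mask on the map grid.
#' @param exclusion_mask optional 3D mask of voxels (necrosis, stalk) to
#'   drop from the VOI.
#' @param n_bins bins for entropy/uniformity.
#' @return named numeric vector of length 252.
#' @export
participant_features <- function(map_set, mask, exclusion_mask = NULL,
                                 n_bins = 64L) {
  stopifnot(inherits(map_set, "param_map_set"))
  gap <- setdiff(metric_catalog()$map, names(map_set$maps))
  if (length(gap))
    stop("map set incomplete, missing: ", paste(gap, collapse = ", "))
  vv <- prod(map_set$voxel_size)
  sel <- mask > 0
  if (!is.null(exclusion_mask)) sel <- sel & !(exclusion_mask > 0)
  if (!any(sel)) stop("VOI empty (after exclusion mask)")
  out <- numeric(0)
  for (nm in names(map_set$maps)) {
    vals <- map_set$maps[[nm]][sel]
    vals <- vals[is.finite(vals)]
    if (length(vals) == 0L)
      stop("map ", nm, ": no finite in-VOI voxels")
    fv <- extract_first_order(vals, voxel_volume = vv, n_bins = n_bins)
    names(fv) <- paste(nm, first_order_names(), sep = "-")
    out <- c(out, fv)
  }
  out
}

#' Assemble the per-participant feature table
#'
#' @param map_sets list of [param_map_set], one per participant.
#' @param masks list of 3D masks, one per participant.
#' @param labels binary labels (0/1), one per participant.
#' @param exclusion_masks optional list of exclusion masks (NULL entries ok).
#' @param ids participant ids (default seq).
#' @param n_bins bins for entropy/uniformity.
#' @return data.frame: `id`, `label`, then 252 feature columns in
#'   deterministic (map catalog x feature) order.
#' @export
build_feature_table <- function(map_sets, masks, labels,
                                exclusion_masks = NULL, ids = NULL,
                                n_bins = 64L) {
  n <- length(map_sets)
  if (length(masks) != n || length(labels) != n)
    stop("map_sets, masks and labels must have one entry per participant")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  if (is.null(ids)) ids <- sprintf("P%03d", seq_len(n))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ex <- if (is.null(exclusion_masks)) NULL else exclusion_masks[[i]]
    rows[[i]] <- tryCatch(
      participant_features(map_sets[[i]], masks[[i]], ex, n_bins),
      error = function(e) stop("participant ", ids[i], ": ",
                               conditionMessage(e), call. = FALSE))
  }
  feat <- do.call(rbind, rows)
  data.frame(id = ids, label = as.integer(labels), feat,
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' Feature-matrix helper: strip id/label columns
#' @param tab a feature table from [build_feature_table()].
#' @return numeric matrix of feature columns.
#' @export
feature_matrix <- function(tab) {
  as.matrix(tab[, setdiff(colnames(tab), c("id", "label", "cohort")),
                drop = FALSE])
}
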