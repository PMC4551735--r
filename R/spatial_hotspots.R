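#' Fixed distance-band binary spatial weights
#'
#' Builds the binary neighbourhood matrix of a point set: \eqn{w_{ij} = 1}
#' when the Euclidean (projected) distance between plots i and j is at most
#' the band distance `d`, boundary inclusive. Self-weights are included only
#' for self-inclusive statistics such as Gi*. Points with no neighbour other
#' than themselves are reported as isolates.
#'
#' @param coords two-column matrix or data frame of projected coordinates (m).
#' @param d band distance in metres, > 0.
#' @param include_self logical; include the diagonal (TRUE for Gi*).
#' @return List of class `band_weights` with the 0/1 matrix `w`, the band `d`,
#'   `include_self`, and integer vector `isolates` (indices with no
#'   neighbours besides self).
#' @export
build_weights <- function(coords, d, include_self = FALSE) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 2) stop("build_weights: need at least 2 points")
  if (d <= 0) stop("build_weights: band distance must be positive")
  dm <- as.matrix(stats::dist(coords))
  w <- (dm <= d) * 1
  isolates <- which(rowSums(w) - 1 == 0)  # only self within band
  if (!include_self) diag(w) <- 0
  structure(list(w = w, d = d, include_self = include_self,
                 isolates = as.integer(isolates)),
            class = "band_weights")
}

#' Global Moran's I with randomization inference
#'
#' \deqn{I = \frac{n}{W} \frac{\sum_i \sum_j w_{ij} z_i z_j}{\sum_i z_i^2}}
#' with \eqn{z_i = x_i - \bar x} and \eqn{W = \sum_{ij} w_{ij}}; self-weights
#' are excluded. The z-score and two-sided p-value use the expectation
#' \eqn{E[I] = -1/(n-1)} and the randomization (permutation-null) variance;
#' a Monte-Carlo permutation p-value is available via `permutations`.
#'
#' @param values numeric vector, not all equal.
#' @param weights a [build_weights()] object (self weights are zeroed).
#' @param permutations if > 0, also compute a permutation p-value with this
#'   many random permutations.
#' @return List with `I`, `expected`, `variance`, `z`, `p` (normal
#'   approximation, two-sided), and optionally `p_perm`.
#' @export
global_morans_i <- function(values, weights, permutations = 0) {
  stopifnot(inherits(weights, "band_weights"))
  w <- weights$w
  diag(w) <- 0
  n <- length(values)
  if (n < 3) stop("global_morans_i: need at least 3 values")
  if (nrow(w) != n) stop("global_morans_i: weights/value length mismatch")
  z <- values - mean(values)
  m2 <- sum(z^2)
  if (m2 == 0) stop("global_morans_i: constant field")
  W <- sum(w)
  I_of <- function(zz) (n / W) * sum(w * outer(zz, zz)) / sum(zz^2)
  I <- I_of(z)
  # randomization variance (Cliff & Ord)
  S1 <- 0.5 * sum((w + t(w))^2)
  S2 <- sum((rowSums(w) + colSums(w))^2)
  b2 <- n * sum(z^4) / m2^2
  EI <- -1 / (n - 1)
  varI <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * W^2) -
           b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * W^2)) /
          ((n - 1) * (n - 2) * (n - 3) * W^2) - EI^2
  zscore <- (I - EI) / sqrt(varI)
  p <- 2 * stats::pnorm(-abs(zscore))
  out <- list(I = I, expected = EI, variance = varI, z = zscore, p = p)
  if (permutations > 0) {
    sims <- vapply(seq_len(permutations), function(k) {
      zz <- sample(z)
      I_of(zz)
    }, numeric(1))
    r <- sum(abs(sims - EI) >= abs(I - EI))
    out$p_perm <- (r + 1) / (permutations + 1)
    out$sims <- sims
  }
  out
}

#' Select the analysis distance band by Global Moran's I
#'
#' Evaluates Moran's I over candidate band distances and returns, among the
#' candidates whose spatial autocorrelation is significant at the 1% level
#' (a 99% likelihood that clustering is real) and under which every plot has
#' at least one neighbour, the one maximizing the Moran z-score. If no
#' candidate qualifies, the outcome is an explicit "no clustering detected".
#'
#' @param values numeric field (e.g. plot LVR).
#' @param coords projected coordinates.
#' @param candidates numeric vector of candidate band distances (m), >= 2.
#' @param alpha significance level for "real clusters" (default 0.01).
#' @return List with `band` (selected distance or NA), `detected` (logical),
#'   and `table` (one row per candidate: d, I, z, p, n_isolates).
#' @export
choose_distance_band <- function(values, coords, candidates, alpha = 0.01) {
  if (length(candidates) < 2)
    stop("choose_distance_band: need at least 2 candidate distances")
  rows <- lapply(sort(candidates), function(d) {
    w <- build_weights(coords, d, include_self = FALSE)
    if (length(w$isolates) > 0)
      return(data.frame(d = d, I = NA_real_, z = NA_real_, p = NA_real_,
                        n_isolates = length(w$isolates)))
    m <- global_morans_i(values, w)
    data.frame(d = d, I = m$I, z = m$z, p = m$p, n_isolates = 0L)
  })
  tab <- do.call(rbind, rows)
  ok <- !is.na(tab$p) & tab$p < alpha & tab$n_isolates == 0
  if (!any(ok))
    return(list(band = NA_real_, detected = FALSE, table = tab))
  best <- tab$d[ok][which.max(tab$z[ok])]
  list(band = best, detected = TRUE, table = tab)
}

#' Getis-Ord Gi* local hotspot statistic
#'
#' Self-inclusive local statistic flagging spatial clusters of high or low
#' values. For plot i with binary band weights \eqn{w_{ij}} (self included):
#' \deqn{z_i = \frac{\sum_j w_{ij} x_j - \bar x \sum_j w_{ij}}
#'   {S \sqrt{\left(n \sum_j w_{ij}^2 - (\sum_j w_{ij})^2\right) / (n-1)}}}
#' with \eqn{\bar x} and S the mean and (population) standard deviation of
#' the full field, point i included. A point whose band contains only itself
#' has an undefined z (NA) and is flagged.
#'
#' @param values numeric field.
#' @param weights a [build_weights()] object built with `include_self = TRUE`.
#' @param permutations if > 0, conditional-permutation p-values (value at i
#'   held fixed, others permuted) with this many draws per point.
#' @return Data frame with `gi_z`, `p_value` (two-sided normal), `isolate`,
#'   and optionally `p_perm`.
#' @export
getis_ord_gi_star <- function(values, weights, permutations = 0) {
  stopifnot(inherits(weights, "band_weights"))
  if (!weights$include_self)
    stop("getis_ord_gi_star: weights must be built with include_self = TRUE")
  w <- weights$w
  n <- length(values)
  if (n < 3) stop("getis_ord_gi_star: need at least 3 values")
  if (nrow(w) != n) stop("getis_ord_gi_star: weights/value length mismatch")
  xbar <- mean(values)
  S <- sqrt(sum(values^2) / n - xbar^2)
  if (S == 0) stop("getis_ord_gi_star: constant field")
  Wi <- rowSums(w)
  S1i <- rowSums(w^2)           # = Wi for binary weights
  num <- as.vector(w %*% values) - xbar * Wi
  den <- S * sqrt(pmax(0, (n * S1i - Wi^2) / (n - 1)))
  z <- ifelse(den > 0, num / den, NA_real_)
  isolate <- Wi <= 1
  z[isolate] <- NA_real_
  out <- data.frame(gi_z = z,
                    p_value = 2 * stats::pnorm(-abs(z)),
                    isolate = isolate)
  if (permutations > 0) {
    gi_num <- function(vals, i) sum(w[i, ] * vals)
    p_perm <- rep(NA_real_, n)
    for (i in which(!isolate)) {
      obs <- gi_num(values, i)
      others <- values[-i]
      sims <- vapply(seq_len(permutations), function(k) {
        v <- values
        v[-i] <- sample(others)
        gi_num(v, i)
      }, numeric(1))
      r <- sum(abs(sims - mean(sims)) >= abs(obs - mean(sims)))
      p_perm[i] <- (r + 1) / (permutations + 1)
    }
    out$p_perm <- p_perm
  }
  out
}

#' Classify Gi* z-scores into five cluster categories
#'
#' Two-sided standard-normal thresholds: |z| >= 2.576 (alpha = 0.01) gives
#' `very_high`/`very_low`, 1.645 <= |z| < 2.576 (alpha = 0.1) gives
#' `high`/`low`, anything else (including undefined z) is `mean`.
#'
#' @param z numeric vector of Gi* z-scores (NA allowed).
#' @return Factor with levels very_low, low, mean, high, very_high.
#' @export
classify_clusters <- function(z) {
  lv <- c("very_low", "low", "mean", "high", "very_high")
  cat <- rep("mean", length(z))
  cat[!is.na(z) & z >= 1.645] <- "high"
  cat[!is.na(z) & z >= 2.576] <- "very_high"
  cat[!is.na(z) & z <= -1.645] <- "low"
  cat[!is.na(z) & z <= -2.576] <- "very_low"
  factor(cat, levels = lv)
}

#' Category colour palette for hotspot maps
#'
#' @return Data frame mapping the five cluster categories to hex colours
#'   (cold blues through hot reds).
#' @export
hotspot_palette <- function() {
  data.frame(category = c("very_low", "low", "mean", "high", "very_high"),
             colour = c("#2166AC", "#92C5DE", "#F7F7F7", "#F4A582", "#B2182B"))
}

#' Write hotspot results as GeoJSON
#'
#' One point feature per plot with properties `plot_id`, `lvr`, `gi_z`, `p`,
#' and `category` (RFC 7946 FeatureCollection). A palette CSV mapping
#' categories to colours is written alongside (same path, `_palette.csv`
#' suffix) for plotting.
#'
#' @param results data frame with `plot_id`, `lvr`, `gi_z`, `p_value`,
#'   `category`.
#' @param coords data frame with `plot_id`, `x`, `y`; keys must match
#'   `results` exactly.
#' @param path output file path (`.geojson`).
#' @return The path, invisibly.
#' @export
write_hotspot_map <- function(results, coords, path) {
  need <- c("plot_id", "lvr", "gi_z", "p_value", "category")
  stopifnot(is.data.frame(results), all(need %in% names(results)))
  if (!setequal(results$plot_id, coords$plot_id) ||
      nrow(results) != nrow(coords))
    stop("write_hotspot_map: results and coords keys do not match")
  coords <- coords[match(results$plot_id, coords$plot_id), ]
  features <- lapply(seq_len(nrow(results)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(coords$x[i], coords$y[i])),
         properties = list(plot_id = results$plot_id[i],
                           lvr = results$lvr[i],
                           gi_z = results$gi_z[i],
                           p = results$p_value[i],
                           category = as.character(results$category[i])))
  })
  doc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, na = "null")
  utils::write.csv(hotspot_palette(),
                   sub("\\.geojson$", "_palette.csv", path), row.names = FALSE)
  invisible(path)
}

#' Run the full hotspot stage
#'
#' Selects the distance band from candidates by Global Moran's I, computes
#' Gi* z-scores with self-inclusive weights at that band, and classifies each
#' plot into the five cluster categories.
#'
#' @param plots data frame with `plot_id`, `x`, `y`, and the LVR field.
#' @param lvr_col name of the LVR column.
#' @param candidates candidate band distances (m).
#' @return List with `band` (selection result) and `results` (per-plot table
#'   with `gi_z`, `p_value`, `category`), or `detected = FALSE` when no band
#'   qualifies.
#' @export
hotspot_analysis <- function(plots, lvr_col = "lvr", candidates) {
  coords <- plots[, c("x", "y")]
  values <- plots[[lvr_col]]
  sel <- choose_distance_band(values, coords, candidates)
  if (!sel$detected)
    return(list(band = sel, detected = FALSE, results = NULL))
  w <- build_weights(coords, sel$band, include_self = TRUE)
  gi <- getis_ord_gi_star(values, w)
  res <- data.frame(plot_id = plots$plot_id, lvr = values,
                    gi_z = gi$gi_z, p_value = gi$p_value,
                    category = classify_clusters(gi$gi_z))
  list(band = sel, detected = TRUE, results = res)
}
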