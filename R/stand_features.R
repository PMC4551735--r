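#' Controlled vocabularies for categorical plot descriptors
#'
#' Stand age classes follow the provincial inventory codes (young/old x
#' even-aged/stratified/uneven-aged); drainage, density and height classes are
#' small ordinal code sets; ecological type and surficial deposit use the code
#' families of the provincial ecological classification.
#'
#' @return Named list of allowed levels per categorical predictor.
#' @export
plot_vocabularies <- function() {
  list(
    age_class = c("JEQ", "JET", "JIN", "VEQ", "VET", "VIN"),
    height_class = c("1", "2", "3", "4"),
    density_class = c("A", "B", "C", "D"),
    drainage_class = c("1", "2", "3", "4", "5", "6"),
    ecotype = c("FC1", "FE1", "FE2", "FE3", "FE4", "FE5", "FE6",
                "MJ1", "MS1", "RT1"),
    deposit = c("1A", "1B", "2", "3", "4", "5", "6", "7", "8", "R")
  )
}

#' Filter merchantable sawlog-bearing trees
#'
#' Retains trees of the target species with DBH strictly greater than the
#' minimum sawlog diameter (23 cm, the lowest merchantable limit of the
#' provincial hardwood grading system); a 23.0 cm tree is excluded. Plots left
#' with no retained tree drop out of the analysis set downstream.
#'
#' @param trees data frame with at least `species` and `dbh_cm` columns.
#' @param species character vector of target species codes.
#' @param dbh_min diameter threshold in cm (exclusive).
#' @return The eligible subset of `trees`, original row order preserved.
#' @export
filter_eligible <- function(trees,
                            species = c("yellow_birch", "sugar_maple"),
                            dbh_min = 23) {
  if (!is.data.frame(trees) || !all(c("species", "dbh_cm") %in% names(trees)))
    stop("filter_eligible: input must have 'species' and 'dbh_cm' columns")
  trees[trees$species %in% species & trees$dbh_cm > dbh_min, , drop = FALSE]
}

#' Exponential Shannon diversity index
#'
#' \eqn{H'_{exp} = \exp(-\sum_i p_i \ln p_i)}, the effective number of equally
#' frequent classes. Equals 1 for a single class and S for S uniform classes;
#' zero-proportion classes contribute nothing.
#'
#' @param proportions non-negative proportions summing to 1 (within `tol`).
#' @param tol tolerance on the sum-to-one check.
#' @return The index value, in \[1, S\].
#' @export
#' @examples
#' shannon_exp(c(0.5, 0.25, 0.25))  # 2^1.5
shannon_exp <- function(proportions, tol = 1e-6) {
  if (any(proportions < 0)) stop("shannon_exp: negative proportion")
  s <- sum(proportions)
  if (!is.finite(s) || s <= 0 || abs(s - 1) > tol)
    stop("shannon_exp: proportions must sum to 1 (got ", format(s), ")")
  p <- proportions[proportions > 0]
  exp(-sum(p * log(p)))
}

#' Species and structural diversity of a plot
#'
#' `species_diversity()` applies the exponential Shannon index to the species
#' shares of a plot's trees; `structural_diversity()` applies it to the shares
#' of DBH classes (2 cm wide by default, the provincial inventory convention).
#' Both are computed over all merchantable trees of the plot, not only the
#' sawlog-eligible ones.
#'
#' @param trees data frame of one plot's trees (`species`, `dbh_cm`).
#' @param class_width DBH class width in cm.
#' @return The diversity index (>= 1).
#' @export
species_diversity <- function(trees) {
  if (nrow(trees) == 0) stop("species_diversity: no trees")
  shannon_exp(as.vector(table(trees$species)) / nrow(trees))
}

#' @rdname species_diversity
#' @export
structural_diversity <- function(trees, class_width = 2) {
  if (nrow(trees) == 0) stop("structural_diversity: no trees")
  cls <- floor(trees$dbh_cm / class_width)
  shannon_exp(as.vector(table(cls)) / nrow(trees))
}

#' Maximum critical load of sulfur and its exceedance
#'
#' The maximum critical load is the sulfur deposition a soil can tolerate
#' without harmful chemical change:
#' \deqn{CL_{max} = BC_{dep} - Cl_{dep} + BC_w - BC_u - Alk_{le(crit)}}
#' (base-cation deposition minus chloride deposition plus base-cation
#' weathering minus net base-cation uptake minus critical alkalinity
#' leaching). Exceedance is actual sulfur deposition minus the critical load.
#' All quantities in eq ha^-1 yr^-1.
#'
#' @param bc_dep sum of K, Ca, Mg, Na deposition rates.
#' @param cl_dep Cl deposition rate.
#' @param bc_w soil base-cation weathering rate.
#' @param bc_u net base-cation uptake rate.
#' @param alk_le_crit critical alkalinity leaching rate.
#' @param s_dep total annual sulfur deposition.
#' @param clmax a critical load as returned by `critical_load()`.
#' @return Critical load (or exceedance) in eq ha^-1 yr^-1.
#' @export
critical_load <- function(bc_dep, cl_dep, bc_w, bc_u, alk_le_crit) {
  vals <- c(bc_dep, cl_dep, bc_w, bc_u, alk_le_crit)
  if (any(!is.finite(vals))) stop("critical_load: inputs must be finite")
  bc_dep - cl_dep + bc_w - bc_u - alk_le_crit
}

#' @rdname critical_load
#' @export
exceedance <- function(s_dep, clmax) {
  if (any(!is.finite(c(s_dep, clmax)))) stop("exceedance: inputs must be finite")
  s_dep - clmax
}

#' Aggregate tree-level LVR to the plot
#'
#' The default aggregation is volume-weighted: total lumber value over total
#' roundwood volume, the plot-scale analogue of the per-tree LVR definition.
#' An unweighted arithmetic mean of tree LVR is available as an option.
#'
#' @param scored data frame of scored trees ([score_trees()] output) with
#'   `plot_id`, `lv`, `lvr`, `roundwood_m3`.
#' @param method "volume" (default) or "mean".
#' @return Data frame with `plot_id` and `lvr` (one row per plot).
#' @export
aggregate_plot_lvr <- function(scored, method = c("volume", "mean")) {
  method <- match.arg(method)
  need <- c("plot_id", "lv", "lvr", "roundwood_m3")
  stopifnot(is.data.frame(scored), all(need %in% names(scored)))
  if (nrow(scored) == 0) stop("aggregate_plot_lvr: no scored trees")
  if (method == "volume") {
    lv <- tapply(scored$lv, scored$plot_id, sum)
    vol <- tapply(scored$roundwood_m3, scored$plot_id, sum)
    out <- data.frame(plot_id = names(lv), lvr = as.vector(lv / vol))
  } else {
    m <- tapply(scored$lvr, scored$plot_id, mean)
    out <- data.frame(plot_id = names(m), lvr = as.vector(m))
  }
  rownames(out) <- NULL
  out
}

#' Build the plot-level feature table
#'
#' Joins plot descriptors to the aggregated LVR response, computing species
#' and structural diversity indices from each plot's full tree list. One table
#' is produced per target species, containing the plots where that species has
#' at least one sawlog-eligible tree; a plot where both species occur appears
#' in both tables. Categorical codes outside the declared vocabularies fail
#' fast with a message listing the offending values.
#'
#' @param plots data frame of plot records (`plot_id`, `x`, `y`, predictors).
#' @param trees data frame of all merchantable trees (`plot_id`, `species`,
#'   `dbh_cm`, grade volumes, `roundwood_m3`).
#' @param qi_par,vsw_par,prices scoring model parameters; `prices` may be a
#'   single [price_table()] or a named list per species.
#' @param species target species to build tables for.
#' @param aggregation passed to [aggregate_plot_lvr()].
#' @return Named list of per-species feature tables (data frames with plot
#'   predictors, diversity indices, and `lvr` response).
#' @export
build_feature_table <- function(plots, trees,
                                qi_par = qi_params(), vsw_par = vsw_params(),
                                prices = NULL,
                                species = c("yellow_birch", "sugar_maple"),
                                aggregation = "volume") {
  stopifnot(is.data.frame(plots), "plot_id" %in% names(plots))
  vocab <- plot_vocabularies()
  for (col in intersect(names(vocab), names(plots))) {
    vals <- as.character(plots[[col]])
    bad <- setdiff(unique(vals[!is.na(vals)]), vocab[[col]])
    if (length(bad))
      stop("build_feature_table: unknown ", col, " code(s): ",
           paste(bad, collapse = ", "))
    plots[[col]] <- factor(vals, levels = vocab[[col]])
  }
  # diversity indices from the full merchantable tree list of each plot
  div <- do.call(rbind, lapply(split(trees, trees$plot_id), function(tt) {
    data.frame(plot_id = tt$plot_id[1],
               spec_div = species_diversity(tt),
               struct_div = structural_diversity(tt))
  }))
  out <- list()
  for (sp in species) {
    ptab <- if (inherits(prices, "price_table")) prices
            else if (is.list(prices) && !is.null(prices[[sp]])) prices[[sp]]
            else default_price_table(sp)
    elig <- filter_eligible(trees, species = sp)
    if (nrow(elig) == 0) {
      out[[sp]] <- plots[0, , drop = FALSE]
      next
    }
    scored <- score_trees(elig, qi_par, vsw_par, ptab)
    resp <- aggregate_plot_lvr(scored, method = aggregation)
    ft <- merge(plots, div, by = "plot_id")
    ft <- merge(ft, resp, by = "plot_id")
    ft <- ft[order(ft$plot_id), , drop = FALSE]
    rownames(ft) <- NULL
    out[[sp]] <- ft
  }
  out
}
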