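## Ecological estimators derived from the fitted model: per-cell richness,
## per-species abundance and area of occupancy, diversity, validation
## benchmarks, and the red-list summary. All estimators use the occupancy
## weight w_ij = m_ij z_ij + (1 - m_ij) psi_hat_ij, i.e. the known state
## where the presence is observed and the model occurrence probability
## elsewhere.

occupancy_weight <- function(fit) {
  if (is.null(fit$psi_hat))
    stop("derived estimators need an integrated-model fit")
  w <- fit$psi_hat
  known <- fit$m == 1
  w[known] <- fit$z_known[known]
  w
}

#' Estimated species richness per cell
#'
#' `S_hat_j = sum_i [ m_ij z_ij + (1 - m_ij) psi_hat_ij ]`: known presences
#' and absences count 0/1, unresolved species contribute their estimated
#' occurrence probability, so species never seen in the plots can still
#' contribute.
#'
#' @param fit A fitted integrated model ([fit_abundance()]).
#' @param cells Cell ids (default: all modelled cells).
#' @return Named numeric vector of estimated richness.
#' @export
estimate_richness <- function(fit, cells = NULL) {
  w <- occupancy_weight(fit)
  j <- resolve_cells(fit, cells)
  setNames(colSums(w[, j, drop = FALSE]), fit$cells$cell[j])
}

#' Estimated species abundance over a set of cells
#'
#' `N_hat_i = sum_{j in cells} d_hat_ij A_j [ m_ij z_ij + (1-m_ij) psi_hat_ij ]`
#' in individuals (density per km^2 times habitat area in km^2).
#'
#' @inheritParams estimate_richness
#' @param cells Subset of cell ids to aggregate over (default: all).
#' @return Named numeric vector, one abundance per species.
#' @export
estimate_abundance <- function(fit, cells = NULL) {
  w <- occupancy_weight(fit)
  j <- resolve_cells(fit, cells)
  if (!length(j)) stop("empty cell subset")
  A <- fit$cells$A[j]
  contrib <- fit$d_hat[, j, drop = FALSE] * w[, j, drop = FALSE]
  setNames(as.numeric(contrib %*% A), fit$species)
}

#' Estimated area of occupancy per species
#'
#' `R_hat_i = sum_j A_j [ m_ij z_ij + (1-m_ij) psi_hat_ij ]` in km^2;
#' bounded above by the total habitat area.
#'
#' @inheritParams estimate_richness
#' @param species Species ids (default: all).
#' @return Named numeric vector of areas of occupancy (km^2).
#' @export
estimate_aoo <- function(fit, species = NULL) {
  w <- occupancy_weight(fit)
  i <- if (is.null(species)) seq_along(fit$species)
       else match(species, fit$species)
  if (any(is.na(i))) stop("unknown species")
  setNames(as.numeric(w[i, , drop = FALSE] %*% fit$cells$A),
           fit$species[i])
}

resolve_cells <- function(fit, cells) {
  if (is.null(cells)) return(seq_len(nrow(fit$cells)))
  j <- match(cells, fit$cells$cell)
  if (any(is.na(j))) stop("unknown cell id(s): ",
                          paste(cells[is.na(j)], collapse = ", "))
  j
}

#' Shannon entropy of an abundance vector
#'
#' `H = -sum q_i log q_i` with `q_i = N_i / sum N` and natural logarithms;
#' zero-abundance entries contribute nothing.
#'
#' @param N Non-negative abundance vector with a positive total.
#' @return Scalar entropy (nats).
#' @examples
#' shannon_entropy(c(1, 1, 1, 1))  # log 4
#' @export
shannon_entropy <- function(N) {
  if (any(N < 0) || any(!is.finite(N))) stop("abundances must be finite and >= 0")
  tot <- sum(N)
  if (tot <= 0) stop("total abundance must be > 0")
  q <- N[N > 0] / tot
  -sum(q * log(q))
}

#' Per-cell summary of the derived estimators
#'
#' @inheritParams estimate_richness
#' @return Data frame with one row per cell: estimated richness, total
#'   abundance and Shannon entropy.
#' @export
cell_estimates <- function(fit) {
  w <- occupancy_weight(fit)
  Nmat <- fit$d_hat * w * matrix(fit$cells$A, nrow(w), ncol(w), byrow = TRUE)
  data.frame(cell = fit$cells$cell,
             richness = colSums(w),
             abundance = colSums(Nmat),
             entropy = apply(Nmat, 2, shannon_entropy))
}

#' Validation benchmarks for predicted densities
#'
#' Root mean square error and bias of the predicted individual density on the
#' arithmetic scale, and the Pearson correlation of log densities over pairs
#' where both prediction and observation are positive. Pairs whose absence is
#' indicated by auxiliary information are expected to be excluded upstream.
#'
#' @param pred,obs Paired density vectors (same length).
#' @return Named vector `(rmse, bias, corr)`.
#' @export
validation_metrics <- function(pred, obs) {
  stopifnot(length(pred) == length(obs))
  ok <- is.finite(pred) & is.finite(obs)
  if (!any(ok)) stop("no valid prediction-observation pairs")
  pred <- pred[ok]; obs <- obs[ok]
  pos <- pred > 0 & obs > 0
  if (sum(pos) < 2)
    stop("correlation of log densities needs at least two positive pairs")
  c(rmse = sqrt(mean((pred - obs)^2)),
    bias = mean(pred - obs),
    corr = cor(log(pred[pos]), log(obs[pos])))
}

#' Red-list summary of abundance and area of occupancy
#'
#' Summarises estimated abundance and area of occupancy by red-list category
#' and flags unlisted ("NC", not classified) native species whose estimated
#' area of occupancy falls below the 20 km^2 threshold of the IUCN D2
#' criterion for Vulnerable. Introduced species are outside the scope of a
#' national red list and are excluded before summarising.
#'
#' @param abundance Named per-species abundance estimates (individuals).
#' @param aoo Named per-species area-of-occupancy estimates (km^2).
#' @param category Character vector of red-list categories per species, in
#'   `c("NC", "NT", "VU", "EN", "CR")`.
#' @param introduced Logical vector: introduced (non-native) species.
#' @param d2_threshold Area threshold (km^2) for the D2 flag.
#' @return List with `table` (per-category distribution of log10 abundance
#'   and area of occupancy) and `flagged` (names of native NC species below
#'   the threshold).
#' @export
redlist_summary <- function(abundance, aoo, category,
                            introduced = rep(FALSE, length(abundance)),
                            d2_threshold = 20) {
  stopifnot(length(abundance) == length(aoo),
            length(category) == length(abundance),
            length(introduced) == length(abundance))
  allowed <- c("NC", "NT", "VU", "EN", "CR")
  if (any(!category[!introduced] %in% allowed))
    stop("unknown red-list category label(s): ",
         paste(setdiff(category[!introduced], allowed), collapse = ", "))
  keep <- !introduced
  ab <- abundance[keep]; ao <- aoo[keep]
  cat_f <- factor(category[keep], levels = allowed)
  qs <- function(x) c(median = median(x), q25 = quantile(x, .25, names = FALSE),
                      q75 = quantile(x, .75, names = FALSE))
  tab <- do.call(rbind, lapply(levels(cat_f), function(cc) {
    i <- cat_f == cc
    if (!any(i))
      return(data.frame(category = cc, n = 0L, log10_abundance = NA,
                        aoo_km2 = NA))
    data.frame(category = cc, n = sum(i),
               log10_abundance = median(log10(pmax(ab[i], 1e-12))),
               aoo_km2 = median(ao[i]))
  }))
  flagged <- names(ao)[cat_f == "NC" & ao < d2_threshold]
  list(table = tab, flagged = flagged[!is.na(flagged)])
}

#' @importFrom stats median var
NULL
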