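#' Summarise one site's simulations into the 15 clustering statistics
#'
#' Per maturity group: the mean rainfed yield over all years and the three
#' initial-moisture conditions (failures counted as 0), and the success rate
#' (proportion of years reaching maturity without a failure rule
#' triggering); plus the mean planting day of year (planting is shared
#' across maturity groups). Sites that never plant get an `NA` planting day.
#'
#' @param results Season-result rows (from [run_factorial]) for a single
#'   site, covering all maturity groups.
#' @param mgs Maturity-group labels expected (default the seven study
#'   groups).
#' @return A one-row data.frame: `site_id`, `yield_<mg>` x 7,
#'   `success_<mg>` x 7, `mean_planting_doy`.
#' @export
summarize_site <- function(results, mgs = default_mg_targets()$mg) {
  stopifnot(length(unique(results$site_id)) == 1L)
  if (!all(mgs %in% results$mg))
    stop("results must cover all maturity groups")
  rainfed <- results[grepl("^rainfed", results$config), , drop = FALSE]
  if (nrow(rainfed) == 0L) stop("no rainfed configurations present")

  yields <- vapply(mgs, function(m)
    mean(rainfed$yield_t_ha[rainfed$mg == m]), numeric(1))
  success <- vapply(mgs, function(m) {
    r <- rainfed[rainfed$mg == m, ]
    # failure status is shared across initial conditions within a year
    mean(tapply(!r$failed, r$year, all))
  }, numeric(1))
  planted <- rainfed$planting_doy[!duplicated(rainfed$year)]
  mean_planting <- if (all(is.na(planted))) NA_real_ else
    mean(planted, na.rm = TRUE)

  out <- data.frame(site_id = results$site_id[1], t(yields), t(success),
                    mean_planting_doy = mean_planting,
                    stringsAsFactors = FALSE)
  names(out) <- c("site_id", paste0("yield_", mgs), paste0("success_", mgs),
                  "mean_planting_doy")
  out
}

#' Summarise every site in a result set
#'
#' @param results Season results from [run_factorial] (any number of sites).
#' @param mgs Maturity-group labels.
#' @return A data.frame with one row per site (see [summarize_site]).
#' @export
summarize_sites <- function(results, mgs = default_mg_targets()$mg) {
  parts <- lapply(split(results, results$site_id), summarize_site, mgs = mgs)
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Distance-band spatial weights
#'
#' Symmetric binary adjacency over sites: an edge wherever the great-circle
#' (haversine, mean Earth radius 6371 km) distance is at most the band;
#' self-edges excluded.
#'
#' @param grid Site data.frame with `lat`, `lon`.
#' @param band_km Distance band in km (default 75).
#' @return A logical adjacency matrix with site ids as dimnames.
#' @export
build_spatial_weights <- function(grid, band_km = 75) {
  n <- nrow(grid)
  if (n < 2) stop("at least two sites are required")
  d <- geosphere::distm(cbind(grid$lon, grid$lat),
                        fun = function(p1, p2)
                          geosphere::distHaversine(p1, p2, r = 6371))
  adj <- d <= band_km
  diag(adj) <- FALSE
  dimnames(adj) <- list(grid$site_id, grid$site_id)
  adj
}

# Connected components of a logical adjacency matrix (BFS).
graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    frontier <- s
    comp[s] <- cur
    while (length(frontier)) {
      nb <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & is.na(comp))
      comp[nb] <- cur
      frontier <- nb
    }
  }
  comp
}

# Min-max normalise columns of a matrix; constant columns are dropped with
# a warning (their range carries no information for the clustering).
minmax_normalize <- function(x) {
  rng <- apply(x, 2, range, na.rm = TRUE)
  span <- rng[2, ] - rng[1, ]
  constant <- span == 0 | !is.finite(span)
  if (any(constant))
    warning("dropping constant variable(s): ",
            paste(colnames(x)[constant], collapse = ", "))
  x <- x[, !constant, drop = FALSE]
  sweep(sweep(x, 2, rng[1, !constant]), 2, span[!constant], "/")
}

#' Spatially constrained Ward clustering of site summaries
#'
#' Bottom-up agglomerative clustering with Ward's minimum-variance criterion
#' on Euclidean distance, after min-max normalisation of every variable,
#' with merges restricted to pairs of clusters adjacent in the spatial
#' weights graph. Every resulting cluster is therefore spatially connected.
#' If the graph has more connected components than requested clusters, each
#' extra component becomes its own cluster and a warning is emitted.
#' Deterministic: ties are broken toward the lowest cluster indices.
#'
#' Sites that never planted have `NA` planting day; it is recoded to the
#' latest possible day of year before normalisation (no planting is the
#' extreme of lateness).
#'
#' @param summaries Site-summary data.frame from [summarize_sites] (first
#'   column `site_id`).
#' @param adjacency Logical adjacency matrix from [build_spatial_weights],
#'   in the same site order.
#' @param n_clusters Number of clusters (default 16).
#' @return Integer cluster labels (1..n_clusters) named by site id.
#' @export
cluster_sites <- function(summaries, adjacency, n_clusters = 16) {
  x <- as.matrix(summaries[, setdiff(names(summaries), "site_id"), drop = FALSE])
  rownames(x) <- summaries$site_id
  if ("mean_planting_doy" %in% colnames(x)) {
    na_pl <- is.na(x[, "mean_planting_doy"])
    x[na_pl, "mean_planting_doy"] <- 366
  }
  n <- nrow(x)
  if (n_clusters < 2 || n_clusters > n)
    stop("n_clusters must be between 2 and the number of sites")
  stopifnot(nrow(adjacency) == n)
  x <- minmax_normalize(x)

  comp <- graph_components(adjacency)
  n_comp <- length(unique(comp))
  if (n_comp > n_clusters) {
    warning(sprintf(paste0("adjacency graph has %d connected components; ",
                           "requested %d clusters, returning one per ",
                           "component"), n_comp, n_clusters))
    n_clusters <- n_comp
  }

  # Lance-Williams Ward agglomeration on squared Euclidean distances,
  # restricted to graph-adjacent cluster pairs.
  d2 <- as.matrix(stats::dist(x))^2
  active <- rep(TRUE, n)
  size <- rep(1L, n)
  adj <- adjacency
  members <- as.list(seq_len(n))
  k <- n
  while (k > n_clusters) {
    dd <- d2
    dd[!adj | !active | !t(matrix(active, n, n))] <- Inf
    dd[lower.tri(dd, diag = TRUE)] <- Inf
    if (!any(is.finite(dd))) break # only disconnected components remain
    ij <- arrayInd(which.min(dd), dim(dd))
    i <- ij[1]; j <- ij[2]
    ni <- size[i]; nj <- size[j]
    # Ward update for every other active cluster h
    h <- which(active); h <- h[h != i & h != j]
    d2[i, h] <- ((ni + size[h]) * d2[i, h] + (nj + size[h]) * d2[j, h] -
                   size[h] * d2[i, j]) / (ni + nj + size[h])
    d2[h, i] <- d2[i, h]
    adj[i, ] <- adj[i, ] | adj[j, ]
    adj[, i] <- adj[, i] | adj[, j]
    adj[i, i] <- FALSE
    active[j] <- FALSE
    size[i] <- ni + nj
    members[[i]] <- c(members[[i]], members[[j]])
    k <- k - 1L
  }
  labels <- integer(n)
  for (ci in seq_along(which(active)))
    labels[members[[which(active)[ci]]]] <- ci
  names(labels) <- rownames(x)
  labels
}

#' Cluster summary table
#'
#' One row per cluster in the style of a regional performance table: for
#' the maturity group with the largest median yield (chosen separately for
#' potential and rainfed yields, ties broken toward the earlier group),
#' the mean and standard deviation of that yield across the cluster's
#' sites, the median success rate, and optionally arable areas joined from
#' a land-use table. Clusters in which every site fails report 0 +/- 0
#' yields, success 0 and maturity group `"na"`.
#'
#' @param labels Cluster labels from [cluster_sites].
#' @param summaries Rainfed site summaries from [summarize_sites].
#' @param potential Optional data.frame of per-site mean potential yields
#'   (columns `site_id` and `yield_<mg>`), e.g. from the potential
#'   configuration via [summarize_potential].
#' @param land_use Optional data.frame with `cluster`, `arable_ha`,
#'   `wheat_pct` to join.
#' @param mgs Maturity-group labels.
#' @return A data.frame, one row per cluster.
#' @export
cluster_summary_table <- function(labels, summaries, potential = NULL,
                                  land_use = NULL,
                                  mgs = default_mg_targets()$mg) {
  stopifnot(length(labels) == nrow(summaries))
  ycol <- paste0("yield_", mgs)
  scol <- paste0("success_", mgs)
  if (!is.null(potential))
    potential <- potential[match(summaries$site_id, potential$site_id), ,
                           drop = FALSE]

  best_block <- function(ym, sm) {
    med <- apply(ym, 2, stats::median)
    if (all(med <= 0))
      return(list(mg = "na", mean = 0, sd = 0, success = 0))
    best <- which.max(med) # which.max takes the first (earliest) on ties
    list(mg = mgs[best], mean = mean(ym[, best]),
         sd = stats::sd(ym[, best]),
         success = stats::median(sm[, best]))
  }

  rows <- lapply(sort(unique(labels)), function(cl) {
    in_cl <- labels == cl
    stopifnot(any(in_cl)) # empty clusters impossible by construction
    rf <- best_block(as.matrix(summaries[in_cl, ycol, drop = FALSE]),
                     as.matrix(summaries[in_cl, scol, drop = FALSE]))
    row <- data.frame(cluster = cl, n_sites = sum(in_cl),
                      rainfed_mean = rf$mean,
                      rainfed_sd = ifelse(is.na(rf$sd), 0, rf$sd),
                      success_pct = 100 * rf$success,
                      mg_rainfed = rf$mg, stringsAsFactors = FALSE)
    if (!is.null(potential)) {
      pm <- as.matrix(potential[in_cl, ycol, drop = FALSE])
      pt <- best_block(pm, as.matrix(summaries[in_cl, scol, drop = FALSE]))
      row$potential_mean <- pt$mean
      row$potential_sd <- ifelse(is.na(pt$sd), 0, pt$sd)
      row$mg_potential <- pt$mg
    }
    row
  })
  out <- do.call(rbind, rows)
  if (!is.null(land_use)) out <- merge(out, land_use, by = "cluster")
  rownames(out) <- NULL
  out
}

#' Per-site mean potential yields by maturity group
#'
#' @param results Season results from [run_factorial].
#' @param mgs Maturity-group labels.
#' @return Data.frame `site_id` plus `yield_<mg>` columns (potential
#'   configuration means over years).
#' @export
summarize_potential <- function(results, mgs = default_mg_targets()$mg) {
  pot <- results[results$config == "potential", , drop = FALSE]
  parts <- lapply(split(pot, pot$site_id), function(r) {
    y <- vapply(mgs, function(m) mean(r$yield_t_ha[r$mg == m]), numeric(1))
    out <- data.frame(site_id = r$site_id[1], t(y), stringsAsFactors = FALSE)
    names(out) <- c("site_id", paste0("yield_", mgs))
    out
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
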