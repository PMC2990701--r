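# Environmental regions: municipalities are grouped into regions of assumed
# homogeneous snake prevalence from altitude, precipitation and location.
# Implemented as Ward-style agglomerative clustering on standardized
# (altitude, precipitation), constrained to merge only clusters that are
# adjacent in a k-nearest-neighbour graph of the municipality centroids, so
# every region is spatially connected by construction.

#' Symmetric k-nearest-neighbour adjacency between municipalities
#'
#' Municipality i and j are adjacent if either is among the other's `k_adj`
#' nearest centroids (Euclidean distance; ties broken by ascending
#' `municipality_id`).
#'
#' @param municipalities Table with `municipality_id`, `centroid_x`,
#'   `centroid_y`.
#' @param k_adj Number of nearest neighbours (default 4).
#' @return Logical adjacency matrix with municipality ids as dimnames.
#' @export
knn_adjacency <- function(municipalities, k_adj = 4L) {
  check_columns(municipalities,
                c("municipality_id", "centroid_x", "centroid_y"),
                "municipalities")
  ids <- municipalities$municipality_id
  n <- length(ids)
  if (any(!is.finite(municipalities$centroid_x)) ||
      any(!is.finite(municipalities$centroid_y))) {
    stop_snakemap("snakemap_schema_error",
                  "missing or non-finite centroid coordinates")
  }
  k_adj <- min(k_adj, n - 1L)
  d <- as.matrix(stats::dist(municipalities[, c("centroid_x", "centroid_y")]))
  adj <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  if (k_adj >= 1L) {
    for (i in seq_len(n)) {
      ord <- order(d[i, ], ids)
      ord <- ord[ord != i]
      nn <- ord[seq_len(k_adj)]
      adj[i, nn] <- TRUE
    }
    adj <- adj | t(adj)
  }
  diag(adj) <- FALSE
  adj
}

# Connected components of a logical adjacency matrix (BFS).
graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0L) {
      v <- queue[1L]
      queue <- queue[-1L]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Assign municipalities to environmental regions
#'
#' Agglomerative (Ward-linkage) clustering of municipalities on z-scored
#' altitude and precipitation, merging only spatially adjacent clusters
#' (adjacency from [knn_adjacency()]), until `k` regions remain. The result
#' is a partition minimizing within-region environmental variance greedily
#' under the contiguity constraint, and is deterministic: ties in merge cost
#' are broken by the lexicographically smallest pair of cluster ids (each
#' cluster identified by its smallest `municipality_id`), and the result does
#' not depend on the input row order.
#'
#' Regions are labelled `R1..Rk` in order of their smallest municipality id.
#'
#' @param municipalities Table with `municipality_id`, `altitude_m`,
#'   `precipitation_mm`, `centroid_x`, `centroid_y`.
#' @param k Target number of regions (default 7).
#' @param weights Named numeric scaling for the standardized features
#'   (default `c(altitude = 1, precipitation = 1)`).
#' @param k_adj Neighbours used for the spatial adjacency graph (default 4).
#' @return `data.frame` of class `region_assignment`
#'   (`municipality_id`, `region`).
#' @export
assign_regions <- function(municipalities, k = 7L,
                           weights = c(altitude = 1, precipitation = 1),
                           k_adj = 4L) {
  check_columns(municipalities,
                c("municipality_id", "altitude_m", "precipitation_mm",
                  "centroid_x", "centroid_y"),
                "municipalities")
  municipalities <- municipalities[order(municipalities$municipality_id), ,
                                   drop = FALSE]
  n <- nrow(municipalities)
  if (k < 1L || k > n) {
    stop_snakemap("snakemap_parameter_error",
                  "k = %d regions is not attainable with %d municipalities",
                  k, n)
  }
  feats <- municipalities[, c("altitude_m", "precipitation_mm")]
  if (any(!is.finite(as.matrix(feats)))) {
    stop_snakemap("snakemap_schema_error",
                  "missing or non-finite altitude/precipitation values")
  }
  z <- scale(as.matrix(feats))
  z[is.nan(z)] <- 0  # zero-variance feature: all municipalities identical
  z <- sweep(z, 2, c(weights[["altitude"]], weights[["precipitation"]]), `*`)

  adj <- knn_adjacency(municipalities, k_adj)
  comp <- graph_components(adj)
  if (max(comp) > k) {
    stop_snakemap("snakemap_parameter_error",
                  "adjacency graph has %d components; cannot form %d connected regions",
                  max(comp), k)
  }

  ids <- municipalities$municipality_id
  members <- as.list(seq_len(n))
  centroid <- z
  sizes <- rep(1L, n)
  min_id <- ids
  active <- rep(TRUE, n)
  cadj <- adj

  ward_cost <- function(a, b) {
    (sizes[a] * sizes[b]) / (sizes[a] + sizes[b]) *
      sum((centroid[a, ] - centroid[b, ])^2)
  }

  n_active <- n
  while (n_active > k) {
    act <- which(active)
    best <- NULL
    best_cost <- Inf
    best_key <- NULL
    for (a in act) {
      nb <- which(cadj[a, ] & active)
      nb <- nb[nb > a]
      for (b in nb) {
        cost <- ward_cost(a, b)
        key <- sort(c(min_id[a], min_id[b]))
        if (cost < best_cost - 1e-12 ||
            (abs(cost - best_cost) <= 1e-12 && !is.null(best_key) &&
             (key[1] < best_key[1] ||
              (key[1] == best_key[1] && key[2] < best_key[2])))) {
          best <- c(a, b)
          best_cost <- cost
          best_key <- key
        }
      }
    }
    if (is.null(best)) {
      # only possible when components > k, which is checked above
      stop_snakemap("snakemap_parameter_error",
                    "no adjacent clusters left to merge")
    }
    a <- best[1]; b <- best[2]
    centroid[a, ] <- (sizes[a] * centroid[a, ] + sizes[b] * centroid[b, ]) /
      (sizes[a] + sizes[b])
    sizes[a] <- sizes[a] + sizes[b]
    members[[a]] <- c(members[[a]], members[[b]])
    min_id[a] <- min(min_id[a], min_id[b])
    cadj[a, ] <- cadj[a, ] | cadj[b, ]
    cadj[, a] <- cadj[, a] | cadj[, b]
    cadj[a, a] <- FALSE
    active[b] <- FALSE
    n_active <- n_active - 1L
  }

  act <- which(active)
  act <- act[order(min_id[act])]
  region <- character(n)
  for (r in seq_along(act)) {
    region[members[[act[r]]]] <- sprintf("R%d", r)
  }
  out <- data.frame(municipality_id = ids, region = region,
                    stringsAsFactors = FALSE)
  class(out) <- c("region_assignment", "data.frame")
  out
}

#' Summarize a region assignment
#'
#' @param assignment A `region_assignment`.
#' @param municipalities Municipality table with `altitude_m` and
#'   `precipitation_mm`.
#' @return `data.frame`: region, number of municipalities, mean altitude (m),
#'   mean annual precipitation (mm).
#' @export
region_summary <- function(assignment, municipalities) {
  check_columns(assignment, c("municipality_id", "region"), "assignment")
  m <- merge(assignment, municipalities, by = "municipality_id")
  agg <- do.call(rbind, lapply(split(m, m$region), function(g) {
    data.frame(region = g$region[1], n = nrow(g),
               mean_altitude_m = mean(g$altitude_m),
               mean_precipitation_mm = mean(g$precipitation_mm),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  agg[order(agg$region), , drop = FALSE]
}

#' Aggregate regions into super-regions
#'
#' Relabels regions according to a grouping map (for instance collapsing the
#' seven environmental regions into East / West / Mountain super-regions for
#' the seasonal curves). Membership counts are conserved: every municipality
#' keeps exactly one label.
#'
#' @param assignment A `region_assignment`.
#' @param grouping Named character vector or list mapping every existing
#'   region label to a super-region label.
#' @return A new `region_assignment` with the super-region labels.
#' @export
aggregate_regions <- function(assignment, grouping) {
  check_columns(assignment, c("municipality_id", "region"), "assignment")
  grouping <- unlist(grouping)
  missing <- setdiff(unique(assignment$region), names(grouping))
  if (length(missing) > 0L) {
    stop_snakemap("snakemap_schema_error",
                  "grouping is missing region label(s): %s",
                  paste(missing, collapse = ", "))
  }
  out <- data.frame(
    municipality_id = assignment$municipality_id,
    region = unname(grouping[assignment$region]),
    stringsAsFactors = FALSE
  )
  class(out) <- c("region_assignment", "data.frame")
  out
}

#' Check that every region is spatially connected
#'
#' Verifies that each region's municipalities form a single connected
#' component of the k-nearest-neighbour adjacency graph restricted to the
#' region.
#'
#' @param assignment A `region_assignment`.
#' @param municipalities Municipality table with centroid coordinates.
#' @param k_adj Neighbours for the adjacency graph (default 4).
#' @return Logical: TRUE if all regions are connected.
#' @export
regions_are_connected <- function(assignment, municipalities, k_adj = 4L) {
  adj <- knn_adjacency(municipalities, k_adj)
  ids <- municipalities$municipality_id
  reg <- assignment$region[match(ids, assignment$municipality_id)]
  all(vapply(unique(reg), function(r) {
    sel <- which(reg == r)
    if (length(sel) == 1L) return(TRUE)
    max(graph_components(adj[sel, sel, drop = FALSE])) == 1L
  }, logical(1)))
}
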