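# Rule-based 3D reconstruction of the granular layer. Cells are placed
# uniformly at random in a box and wired by anatomical convergence /
# divergence rules:
#   * each granule cell (GRC) sends exactly 4 dendrites to 4 distinct
#     glomeruli (GLOs) within 40 um, at most one dendrite per GLO;
#   * GLO -> GRC divergence targets 1:53 (enforced as a per-GLO capacity while
#     feasible; see connect_grc_dendrites for the saturation behaviour);
#   * each Golgi cell (GOC) dendritic tree samples 50 distinct GLOs;
#   * each GOC axon inhibits at most 40 distinct GLOs, and a GRC is never
#     inhibited twice by the same GOC;
#   * each GOC receives 400 ascending-axon and 1000 parallel-fiber GRC inputs.
# Every connection carries a propagation delay drawn once at build time.

#' Volume specification
#'
#' @param x,y,z box edge lengths (um), all > 0. `y` is the depth axis used by
#'   the ascending-axon column rule.
#' @return Object of class `volume_spec`.
#' @export
volume_spec <- function(x, y, z) {
  if (any(c(x, y, z) <= 0)) stop("volume_spec: edges must be > 0")
  structure(list(x = x, y = y, z = z), class = "volume_spec")
}

#' Cell density configuration
#'
#' Defaults reproduce the reference network sizes (e.g. 108,000 GRCs, 243
#' GOCs and 8100 GLOs in 300 x 75 x 1200 um^3): 4.0e-3 GRC/um^3, 9.0e-6
#' GOC/um^3, 3.0e-4 GLO/um^3, and 20 glomeruli per mossy fiber.
#'
#' @param rho_grc,rho_goc,rho_glo densities (cells per um^3), > 0.
#' @param mf_per_glo_ratio glomeruli per mossy fiber, >= 1.
#' @return Object of class `density_config`.
#' @export
density_config <- function(rho_grc = 4.0e-3, rho_goc = 9.0e-6,
                           rho_glo = 3.0e-4, mf_per_glo_ratio = 20) {
  if (any(c(rho_grc, rho_goc, rho_glo) <= 0))
    stop("density_config: densities must be > 0")
  if (mf_per_glo_ratio < 1)
    stop("density_config: mf_per_glo_ratio must be >= 1")
  structure(list(rho_grc = rho_grc, rho_goc = rho_goc, rho_glo = rho_glo,
                 mf_per_glo_ratio = mf_per_glo_ratio),
            class = "density_config")
}

#' Wiring rule configuration
#'
#' @param grc_dendrites dendrites per granule cell (4).
#' @param grc_dendrite_max_dist maximum dendrite reach (um, 40).
#' @param glo_grc_capacity target granule-dendrite capacity per glomerulus
#'   (53).
#' @param glo_per_goc_dendrite glomeruli sampled by each Golgi dendritic tree
#'   (50).
#' @param goc_axon_max_glo maximum glomeruli inhibited by one Golgi axon (40).
#' @param aa_per_goc ascending-axon convergence onto each Golgi cell (400).
#' @param pf_per_goc parallel-fiber convergence onto each Golgi cell (1000).
#' @param goc_dendrite_radius Golgi dendritic sampling radius (um, 100).
#' @param goc_axon_radius Golgi axonal sampling radius (um, 150).
#' @param aa_column_radius lateral (x-z) radius of the ascending-axon column
#'   (um, 50).
#' @param relax_step distance-relaxation increment (um, 10); 0 disables
#'   relaxation.
#' @param relax_cap_um extra reach beyond `grc_dendrite_max_dist` within which
#'   capacity overflow may be used once every in-range glomerulus is full
#'   (um, 40).
#' @param allow_overflow allow least-loaded capacity overflow when all
#'   in-range glomeruli are saturated (logged in the audit); if `FALSE` the
#'   build errors instead.
#' @param delay_range propagation-delay bounds (ms), drawn once per connection.
#' @return Object of class `rule_config`.
#' @export
rule_config <- function(grc_dendrites = 4L,
                        grc_dendrite_max_dist = 40,
                        glo_grc_capacity = 53L,
                        glo_per_goc_dendrite = 50L,
                        goc_axon_max_glo = 40L,
                        aa_per_goc = 400L,
                        pf_per_goc = 1000L,
                        goc_dendrite_radius = 100,
                        goc_axon_radius = 150,
                        aa_column_radius = 50,
                        relax_step = 10,
                        relax_cap_um = 40,
                        allow_overflow = TRUE,
                        delay_range = c(0.1, 1.0)) {
  ints <- c(grc_dendrites, glo_grc_capacity, glo_per_goc_dendrite,
            goc_axon_max_glo, aa_per_goc, pf_per_goc)
  if (any(ints < 1) || any(ints != round(ints)))
    stop("rule_config: counts must be positive integers")
  if (any(c(grc_dendrite_max_dist, goc_dendrite_radius, goc_axon_radius,
            aa_column_radius) <= 0))
    stop("rule_config: radii must be > 0")
  if (delay_range[1] <= 0 || delay_range[2] < delay_range[1])
    stop("rule_config: invalid delay_range")
  structure(list(grc_dendrites = as.integer(grc_dendrites),
                 grc_dendrite_max_dist = grc_dendrite_max_dist,
                 glo_grc_capacity = as.integer(glo_grc_capacity),
                 glo_per_goc_dendrite = as.integer(glo_per_goc_dendrite),
                 goc_axon_max_glo = as.integer(goc_axon_max_glo),
                 aa_per_goc = as.integer(aa_per_goc),
                 pf_per_goc = as.integer(pf_per_goc),
                 goc_dendrite_radius = goc_dendrite_radius,
                 goc_axon_radius = goc_axon_radius,
                 aa_column_radius = aa_column_radius,
                 relax_step = relax_step,
                 relax_cap_um = relax_cap_um,
                 allow_overflow = isTRUE(allow_overflow),
                 delay_range = delay_range),
            class = "rule_config")
}

#' Population counts from volume and densities
#'
#' Each population count is `round(rho * V)`; the mossy-fiber count is
#' `ceiling(n_glo / mf_per_glo_ratio)`.
#'
#' @param volume a [volume_spec()].
#' @param densities a [density_config()].
#' @return List with `n_goc`, `n_grc`, `n_glo`, `n_mf` (integers).
#' @export
sample_counts <- function(volume, densities = density_config()) {
  stopifnot(inherits(volume, "volume_spec"), inherits(densities, "density_config"))
  v <- volume$x * volume$y * volume$z
  n_goc <- as.integer(round(densities$rho_goc * v))
  n_grc <- as.integer(round(densities$rho_grc * v))
  n_glo <- as.integer(round(densities$rho_glo * v))
  if (n_goc < 1 || n_glo < 1)
    stop("sample_counts: volume too small for at least one GOC and one GLO; ",
         "use a larger volume or override the counts explicitly")
  n_mf <- as.integer(ceiling(n_glo / densities$mf_per_glo_ratio))
  list(n_goc = n_goc, n_grc = n_grc, n_glo = n_glo, n_mf = n_mf)
}

#' Place cells uniformly in the volume
#'
#' @param counts output of [sample_counts()].
#' @param volume a [volume_spec()].
#' @param seed optional integer seed.
#' @return List of position matrices `goc`, `grc`, `glo` (n x 3, columns
#'   x, y, z in um).
#' @export
place_cells <- function(counts, volume, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  place <- function(n) {
    m <- cbind(x = stats::runif(n, 0, volume$x),
               y = stats::runif(n, 0, volume$y),
               z = stats::runif(n, 0, volume$z))
    m
  }
  list(goc = place(counts$n_goc), grc = place(counts$n_grc),
       glo = place(counts$n_glo))
}

#' Assign glomeruli to mossy fibers
#'
#' Random balanced partition: glomerulus ids are shuffled and split into
#' near-equal contiguous blocks, one per fiber, so fiber loads differ by at
#' most one.
#'
#' @param n_glo number of glomeruli.
#' @param ratio glomeruli per mossy fiber, >= 1.
#' @param seed optional integer seed.
#' @return Integer vector of length `n_glo`: the mossy-fiber id of each
#'   glomerulus (1-based).
#' @export
assign_mfs <- function(n_glo, ratio = 20, seed = NULL) {
  if (ratio < 1) stop("assign_mfs: ratio must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  n_mf <- as.integer(ceiling(n_glo / ratio))
  perm <- sample.int(n_glo)
  sizes <- rep(n_glo %/% n_mf, n_mf)
  extra <- n_glo - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  mf <- integer(n_glo)
  mf[perm] <- rep.int(seq_len(n_mf), sizes)
  mf
}

# squared distances from one point to a matrix of points
d2_to <- function(p, pts) {
  (pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2 + (pts[, 3] - p[3])^2
}

# uniform grid over glo positions; returns per-bin candidate unions so a
# query point's in-range candidates are found in O(candidates)
make_glo_grid <- function(glo, volume, cell) {
  dims <- pmax(1L, as.integer(ceiling(c(volume$x, volume$y, volume$z) / cell)))
  bin3 <- function(pts) {
    b <- cbind(pmin(dims[1] - 1L, as.integer(pts[, 1] / cell)),
               pmin(dims[2] - 1L, as.integer(pts[, 2] / cell)),
               pmin(dims[3] - 1L, as.integer(pts[, 3] / cell)))
    b[, 1] + dims[1] * (b[, 2] + dims[2] * b[, 3]) + 1L
  }
  list(cell = cell, dims = dims, bin3 = bin3,
       members = split(seq_len(nrow(glo)), bin3(glo)))
}

# glo ids in the 27-neighborhood of a linear bin id
grid_neighborhood <- function(grid, bin_id) {
  d <- grid$dims
  b0 <- bin_id - 1L
  bx <- b0 %% d[1]; by <- (b0 %/% d[1]) %% d[2]; bz <- b0 %/% (d[1] * d[2])
  out <- integer(0)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    x <- bx + dx; y <- by + dy; z <- bz + dz
    if (x < 0 || y < 0 || z < 0 || x >= d[1] || y >= d[2] || z >= d[3]) next
    key <- as.character(x + d[1] * (y + d[2] * z) + 1L)
    m <- grid$members[[key]]
    if (!is.null(m)) out <- c(out, m)
  }
  out
}

#' Wire granule-cell dendrites to glomeruli
#'
#' Each granule cell receives exactly `grc_dendrites` (4) distinct glomerular
#' targets chosen uniformly at random among glomeruli within
#' `grc_dendrite_max_dist` (40 um) whose dendrite load is below
#' `glo_grc_capacity` (53). A cell with too few eligible glomeruli widens its
#' search radius in `relax_step` (10 um) increments (logged). At the default
#' densities total dendrite demand slightly exceeds total glomerular capacity
#' (mean load 53.3), so once every glomerulus within
#' `grc_dendrite_max_dist + relax_cap_um` is saturated the least-loaded
#' in-range glomeruli are used and the overflow is logged in the audit; set
#' `allow_overflow = FALSE` to make saturation an error instead.
#'
#' @param positions output of [place_cells()].
#' @param rules a [rule_config()].
#' @param volume the [volume_spec()] the positions were drawn in.
#' @param seed optional integer seed.
#' @return List with `edges` (data.frame `grc`, `glo`, `slot` 1..4,
#'   `delay_ms`), `load` (dendrites per glomerulus) and `log`
#'   (relaxation/overflow statistics).
#' @export
connect_grc_dendrites <- function(positions, rules = rule_config(), volume,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  grc <- positions$grc
  glo <- positions$glo
  n_grc <- nrow(grc)
  n_glo <- nrow(glo)
  k <- rules$grc_dendrites
  if (n_glo < k)
    stop("connect_grc_dendrites: fewer glomeruli than dendrites per cell")
  r0 <- rules$grc_dendrite_max_dist
  cap <- rules$glo_grc_capacity
  diag_len <- sqrt(volume$x^2 + volume$y^2 + volume$z^2)

  # precompute in-range candidate lists, chunked by grid bin
  grid <- make_glo_grid(glo, volume, cell = r0)
  grc_bin <- grid$bin3(grc)
  cand <- vector("list", n_grc)
  for (b in unique(grc_bin)) {
    ids <- which(grc_bin == b)
    pool <- grid_neighborhood(grid, b)
    if (!length(pool)) next
    a <- grc[ids, , drop = FALSE]
    p <- glo[pool, , drop = FALSE]
    d2 <- outer(rowSums(a^2), rowSums(p^2), "+") - 2 * (a %*% t(p))
    for (j in seq_along(ids)) cand[[ids[j]]] <- pool[d2[j, ] <= r0^2 + 1e-9]
  }

  load <- integer(n_glo)
  tgt <- matrix(0L, nrow = n_grc, ncol = k)
  n_relaxed <- 0L
  max_radius_used <- r0
  n_overflow <- 0L
  for (i in seq_len(n_grc)) {
    cc <- cand[[i]]
    open <- cc[load[cc] < cap]
    if (length(open) >= k) {
      pick <- open[sample.int(length(open), k)]
    } else {
      # relaxation ladder
      r <- r0
      pick <- NULL
      relaxed <- FALSE
      repeat {
        if (length(open) >= k) {
          pick <- open[sample.int(length(open), k)]
          break
        }
        if (length(cc) >= k && r >= r0 + rules$relax_cap_um) {
          if (!rules$allow_overflow)
            stop("connect_grc_dendrites: glomerular capacity saturated for GRC ",
                 i, " and overflow is disabled")
          need <- k - length(open)
          rest <- setdiff(cc, open)
          fill <- rest[order(load[rest], rest)][seq_len(need)]
          pick <- c(if (length(open)) open[sample.int(length(open), length(open))],
                    fill)
          n_overflow <- n_overflow + need
          break
        }
        if (rules$relax_step <= 0)
          stop("connect_grc_dendrites: GRC ", i, " has fewer than ", k,
               " eligible glomeruli and relaxation is disabled")
        if (r > diag_len)
          stop("connect_grc_dendrites: GRC ", i, " cannot reach ", k,
               " glomeruli anywhere in the volume")
        r <- r + rules$relax_step
        relaxed <- TRUE
        d2i <- d2_to(grc[i, ], glo)
        cc <- which(d2i <= r^2 + 1e-9)
        open <- cc[load[cc] < cap]
      }
      if (relaxed) {
        n_relaxed <- n_relaxed + 1L
        max_radius_used <- max(max_radius_used, r)
      }
    }
    load[pick] <- load[pick] + 1L
    tgt[i, ] <- pick
  }
  edges <- data.frame(grc = rep(seq_len(n_grc), each = k),
                      glo = as.integer(t(tgt)),
                      slot = rep.int(seq_len(k), n_grc),
                      delay_ms = stats::runif(n_grc * k, rules$delay_range[1],
                                              rules$delay_range[2]))
  list(edges = edges, load = load,
       log = list(n_relaxed = n_relaxed, max_radius_used = max_radius_used,
                  n_overflow = n_overflow, max_load = max(load)))
}

#' Wire Golgi dendrites to glomeruli
#'
#' Each Golgi cell samples `glo_per_goc_dendrite` (50) distinct glomeruli
#' uniformly within `goc_dendrite_radius` (100 um), widening the radius in
#' `relax_step` increments when the pool is too small. The resulting number of
#' distinct mossy fibers per Golgi cell (about 40 at the default fiber ratio)
#' is an emergent audit statistic, not an enforced rule.
#'
#' @inheritParams connect_grc_dendrites
#' @return List with `edges` (data.frame `glo`, `goc`, `slot` = 1,
#'   `delay_ms`) and `log`.
#' @export
connect_goc_dendrites <- function(positions, rules = rule_config(), volume,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  goc <- positions$goc
  glo <- positions$glo
  n_goc <- nrow(goc)
  n_glo <- nrow(glo)
  k <- rules$glo_per_goc_dendrite
  if (n_glo < k)
    stop("connect_goc_dendrites: fewer glomeruli (", n_glo,
         ") than the Golgi dendritic convergence (", k, ")")
  diag_len <- sqrt(volume$x^2 + volume$y^2 + volume$z^2)
  n_relaxed <- 0L
  max_radius_used <- rules$goc_dendrite_radius
  src <- matrix(0L, nrow = n_goc, ncol = k)
  for (i in seq_len(n_goc)) {
    d2i <- d2_to(goc[i, ], glo)
    r <- rules$goc_dendrite_radius
    cc <- which(d2i <= r^2 + 1e-9)
    relaxed <- FALSE
    while (length(cc) < k) {
      if (rules$relax_step <= 0 || r > diag_len)
        stop("connect_goc_dendrites: GOC ", i, " cannot reach ", k, " glomeruli")
      r <- r + rules$relax_step
      relaxed <- TRUE
      cc <- which(d2i <= r^2 + 1e-9)
    }
    if (relaxed) {
      n_relaxed <- n_relaxed + 1L
      max_radius_used <- max(max_radius_used, r)
    }
    src[i, ] <- cc[sample.int(length(cc), k)]
  }
  edges <- data.frame(glo = as.integer(t(src)),
                      goc = rep(seq_len(n_goc), each = k),
                      slot = 1L,
                      delay_ms = stats::runif(n_goc * k, rules$delay_range[1],
                                              rules$delay_range[2]))
  list(edges = edges,
       log = list(n_relaxed = n_relaxed, max_radius_used = max_radius_used))
}

#' Wire Golgi axons to glomeruli and expand to granule-cell inhibition
#'
#' Each Golgi axon selects up to `goc_axon_max_glo` (40) distinct glomeruli
#' within `goc_axon_radius` (150 um) — a maximum, so cells with fewer
#' reachable glomeruli are not an error. Every selected glomerulus expands to
#' an inhibitory edge onto each granule cell sending a dendrite into it, on
#' the inhibitory receptor slot paired with that dendrite; duplicate
#' (GOC, GRC) pairs are dropped keeping the first encountered, so no granule
#' cell is inhibited twice by the same Golgi cell.
#'
#' @inheritParams connect_grc_dendrites
#' @param edges_grc_glo the granule-dendrite edge table from
#'   [connect_grc_dendrites()].
#' @return List with `edges_axon` (data.frame `goc`, `glo`), `edges_inh`
#'   (data.frame `goc`, `grc`, `slot` 5..8, `delay_ms`) and `log`.
#' @export
connect_goc_axon <- function(positions, edges_grc_glo, rules = rule_config(),
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  goc <- positions$goc
  glo <- positions$glo
  n_goc <- nrow(goc)
  kmax <- rules$goc_axon_max_glo
  n_exc_slots <- rules$grc_dendrites  # inhibitory slot s pairs with dendrite s
  by_glo <- split(seq_len(nrow(edges_grc_glo)), edges_grc_glo$glo)
  ax_goc <- vector("list", n_goc)
  ax_glo <- vector("list", n_goc)
  inh <- vector("list", n_goc)
  for (i in seq_len(n_goc)) {
    d2i <- d2_to(goc[i, ], glo)
    cc <- which(d2i <= rules$goc_axon_radius^2 + 1e-9)
    if (!length(cc)) next
    kk <- min(kmax, length(cc))
    pick <- cc[sample.int(length(cc), kk)]
    ax_goc[[i]] <- rep.int(i, kk)
    ax_glo[[i]] <- pick
    rows <- unlist(by_glo[as.character(pick)], use.names = FALSE)
    if (!length(rows)) next
    grcs <- edges_grc_glo$grc[rows]
    slots <- edges_grc_glo$slot[rows]
    keep <- !duplicated(grcs)
    inh[[i]] <- data.frame(goc = i, grc = grcs[keep],
                           slot = n_exc_slots + slots[keep])
  }
  edges_axon <- data.frame(goc = unlist(ax_goc, use.names = FALSE),
                           glo = unlist(ax_glo, use.names = FALSE))
  edges_inh <- do.call(rbind, inh[!vapply(inh, is.null, logical(1))])
  if (is.null(edges_inh))
    edges_inh <- data.frame(goc = integer(0), grc = integer(0), slot = integer(0))
  edges_inh$delay_ms <- stats::runif(nrow(edges_inh), rules$delay_range[1],
                                     rules$delay_range[2])
  rownames(edges_inh) <- NULL
  list(edges_axon = edges_axon, edges_inh = edges_inh,
       log = list(max_glo_per_axon = if (nrow(edges_axon))
         max(tabulate(edges_axon$goc, n_goc)) else 0L))
}

#' Wire granule-cell excitation onto Golgi cells
#'
#' Each Golgi cell receives `aa_per_goc` (400) distinct ascending-axon inputs
#' sampled among granule cells within a vertical column (lateral x-z distance
#' at most `aa_column_radius`, 50 um) and `pf_per_goc` (1000) distinct
#' parallel-fiber inputs sampled from the whole volume. Requested counts are
#' clipped to the eligible pool with a warning. Both pathways target the
#' Golgi excitatory receptor slot reserved for granule-cell input (slot 2;
#' slot 1 receives mossy-fiber input through the glomeruli).
#'
#' @inheritParams connect_grc_dendrites
#' @return List with `edges` (data.frame `grc`, `goc`, `slot` = 2, `pathway`
#'   "aa" or "pf", `delay_ms`) and `log`.
#' @export
connect_grc_to_goc <- function(positions, rules = rule_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  goc <- positions$goc
  grc <- positions$grc
  n_goc <- nrow(goc)
  n_grc <- nrow(grc)
  if (n_grc == 0) stop("connect_grc_to_goc: no granule cells")
  out <- vector("list", n_goc)
  aa_clipped <- 0L
  pf_clipped <- 0L
  for (i in seq_len(n_goc)) {
    lat2 <- (grc[, 1] - goc[i, 1])^2 + (grc[, 3] - goc[i, 3])^2
    col_ids <- which(lat2 <= rules$aa_column_radius^2 + 1e-9)
    n_aa <- min(rules$aa_per_goc, length(col_ids))
    if (n_aa < rules$aa_per_goc) aa_clipped <- aa_clipped + 1L
    aa <- if (n_aa) col_ids[sample.int(length(col_ids), n_aa)] else integer(0)
    n_pf <- min(rules$pf_per_goc, n_grc)
    if (n_pf < rules$pf_per_goc) pf_clipped <- pf_clipped + 1L
    pf <- if (n_pf) sample.int(n_grc, n_pf) else integer(0)
    out[[i]] <- data.frame(grc = c(aa, pf), goc = i, slot = 2L,
                           pathway = rep(c("aa", "pf"), c(n_aa, n_pf)))
  }
  edges <- do.call(rbind, out)
  rownames(edges) <- NULL
  edges$delay_ms <- stats::runif(nrow(edges), rules$delay_range[1],
                                 rules$delay_range[2])
  if (aa_clipped + pf_clipped > 0)
    warning("connect_grc_to_goc: convergence clipped to the eligible pool for ",
            aa_clipped, " (aa) / ", pf_clipped, " (pf) Golgi cells")
  list(edges = edges, log = list(aa_clipped = aa_clipped, pf_clipped = pf_clipped))
}

#' Build a complete granular-layer network
#'
#' Runs the five wiring stages in a fixed order (placement, mossy-fiber
#' assignment, granule dendrites, Golgi dendrites, Golgi axon, granule-to-
#' Golgi excitation) under a single seed and validates the hard wiring
#' invariants before returning. The attached audit reports min/mean/max
#' statistics for every rule.
#'
#' @param volume a [volume_spec()] or preset name accepted by
#'   [network_preset()].
#' @param densities a [density_config()].
#' @param rules a [rule_config()].
#' @param seed integer seed; the whole build is reproducible from it.
#' @param quiet suppress progress messages.
#' @return Object of class `gl_network`: positions, `glo_to_mf`, the five edge
#'   tables, `counts`, configuration and `audit`.
#' @export
build_network <- function(volume, densities = density_config(),
                          rules = rule_config(), seed = 1, quiet = TRUE) {
  if (is.character(volume)) {
    p <- network_preset(volume)
    volume <- p$volume
    densities <- p$densities
  }
  set.seed(seed)
  say <- function(...) if (!quiet) message(...)
  counts <- sample_counts(volume, densities)
  say("placing ", counts$n_grc, " GRCs, ", counts$n_goc, " GOCs, ",
      counts$n_glo, " GLOs (", counts$n_mf, " MFs)")
  positions <- place_cells(counts, volume)
  glo_to_mf <- assign_mfs(counts$n_glo, densities$mf_per_glo_ratio)
  say("wiring granule dendrites")
  dd <- connect_grc_dendrites(positions, rules, volume)
  say("wiring Golgi dendrites")
  gd <- connect_goc_dendrites(positions, rules, volume)
  say("wiring Golgi axons")
  ax <- connect_goc_axon(positions, dd$edges, rules)
  say("wiring granule-to-Golgi excitation")
  gg <- connect_grc_to_goc(positions, rules)
  net <- structure(list(
    positions = positions,
    glo_to_mf = glo_to_mf,
    edges_grc_glo = dd$edges,
    edges_glo_goc_dend = gd$edges,
    edges_goc_glo_axon = ax$edges_axon,
    edges_goc_grc_inh = ax$edges_inh,
    edges_grc_goc_exc = gg$edges,
    counts = counts,
    volume = volume,
    densities = densities,
    rules = rules,
    seed = seed,
    build_log = list(grc_dendrites = dd$log, goc_dendrites = gd$log,
                     goc_axon = ax$log, grc_goc = gg$log)
  ), class = "gl_network")
  validate_network(net)
  net$audit <- audit_network(net)
  net
}

#' Validate the hard wiring invariants of a network
#'
#' Stops on the first violated invariant: exactly `grc_dendrites` distinct
#' glomeruli per granule cell, unique (GRC, GLO) pairs, unique (GOC, GRC)
#' inhibitory pairs, at most `goc_axon_max_glo` glomeruli per Golgi axon,
#' exactly `glo_per_goc_dendrite` distinct glomeruli per Golgi dendritic tree
#' and duplicate-free aa/pf source sets.
#'
#' @param net a `gl_network`.
#' @return `net`, invisibly.
#' @export
validate_network <- function(net) {
  r <- net$rules
  e <- net$edges_grc_glo
  per_grc <- tabulate(e$grc, net$counts$n_grc)
  if (any(per_grc != r$grc_dendrites))
    stop("validate_network: some GRC does not have exactly ",
         r$grc_dendrites, " dendrites")
  if (anyDuplicated(e[c("grc", "glo")]))
    stop("validate_network: duplicate (GRC, GLO) dendrite pair")
  if (anyDuplicated(net$edges_goc_grc_inh[c("goc", "grc")]))
    stop("validate_network: a GRC is inhibited twice by the same GOC")
  if (nrow(net$edges_goc_glo_axon)) {
    per_axon <- tabulate(net$edges_goc_glo_axon$goc, net$counts$n_goc)
    if (max(per_axon) > r$goc_axon_max_glo)
      stop("validate_network: a GOC axon exceeds ", r$goc_axon_max_glo, " GLOs")
    if (anyDuplicated(net$edges_goc_glo_axon))
      stop("validate_network: duplicate (GOC, GLO) axonal pair")
  }
  gd <- net$edges_glo_goc_dend
  per_goc <- tabulate(gd$goc, net$counts$n_goc)
  if (any(per_goc != r$glo_per_goc_dendrite))
    stop("validate_network: some GOC dendritic tree does not sample exactly ",
         r$glo_per_goc_dendrite, " GLOs")
  if (anyDuplicated(gd[c("goc", "glo")]))
    stop("validate_network: duplicate (GOC, GLO) dendritic pair")
  gg <- net$edges_grc_goc_exc
  if (anyDuplicated(gg[c("goc", "grc", "pathway")]))
    stop("validate_network: duplicate source within an aa/pf pathway")
  if (length(net$glo_to_mf) != net$counts$n_glo || anyNA(net$glo_to_mf))
    stop("validate_network: every GLO must map to exactly one MF")
  invisible(net)
}

#' Connectivity audit of a built network
#'
#' Per-rule min/mean/max statistics: dendrites per glomerulus (with capacity
#' overflow and relaxation counts), dendrite lengths, distinct mossy fibers
#' per Golgi cell, glomeruli per Golgi axon, inhibitory in-degree per granule
#' cell, and aa/pf convergence.
#'
#' @param net a `gl_network`.
#' @return Object of class `gl_audit` (a list of statistics) with a print
#'   method.
#' @export
audit_network <- function(net) {
  cn <- net$counts
  stat3 <- function(x) c(min = min(x), mean = mean(x), max = max(x))
  e <- net$edges_grc_glo
  load <- tabulate(e$glo, cn$n_glo)
  dist_grc_glo <- sqrt(rowSums((net$positions$grc[e$grc, , drop = FALSE] -
                                  net$positions$glo[e$glo, , drop = FALSE])^2))
  gd <- net$edges_glo_goc_dend
  mf_per_goc <- vapply(split(net$glo_to_mf[gd$glo], gd$goc),
                       function(m) length(unique(m)), integer(1))
  inh_in <- tabulate(net$edges_goc_grc_inh$grc, cn$n_grc)
  gg <- net$edges_grc_goc_exc
  aa_n <- tabulate(gg$goc[gg$pathway == "aa"], cn$n_goc)
  pf_n <- tabulate(gg$goc[gg$pathway == "pf"], cn$n_goc)
  out <- list(
    counts = cn,
    dendrites_per_glo = stat3(load),
    mean_dendrites_per_glo = mean(load),
    capacity = net$rules$glo_grc_capacity,
    n_glo_over_capacity = sum(load > net$rules$glo_grc_capacity),
    overflow_assignments = net$build_log$grc_dendrites$n_overflow,
    n_grc_relaxed = net$build_log$grc_dendrites$n_relaxed,
    max_dendrite_radius = net$build_log$grc_dendrites$max_radius_used,
    dendrite_length = stat3(dist_grc_glo),
    distinct_mf_per_goc = stat3(mf_per_goc),
    glo_per_goc_axon = if (nrow(net$edges_goc_glo_axon))
      stat3(tabulate(net$edges_goc_glo_axon$goc, cn$n_goc)) else c(min = 0, mean = 0, max = 0),
    inh_in_degree_grc = stat3(inh_in),
    aa_per_goc = stat3(aa_n),
    pf_per_goc = stat3(pf_n),
    delay_range = range(c(e$delay_ms, gd$delay_ms,
                          net$edges_goc_grc_inh$delay_ms, gg$delay_ms))
  )
  structure(out, class = "gl_audit")
}

#' @export
print.gl_audit <- function(x, ...) {
  cat("granular-layer connectivity audit\n")
  cat(sprintf("  populations: %d GOC, %d GRC, %d GLO, %d MF\n",
              x$counts$n_goc, x$counts$n_grc, x$counts$n_glo, x$counts$n_mf))
  f3 <- function(s) sprintf("min %.4g / mean %.4g / max %.4g", s[1], s[2], s[3])
  cat("  dendrites per GLO:       ", f3(x$dendrites_per_glo),
      sprintf(" (capacity %d, %d over, %d overflow assignments)\n",
              x$capacity, x$n_glo_over_capacity, x$overflow_assignments))
  cat("  dendrite length (um):    ", f3(x$dendrite_length),
      sprintf(" (%d GRCs relaxed, max radius %.4g)\n",
              x$n_grc_relaxed, x$max_dendrite_radius))
  cat("  distinct MFs per GOC:    ", f3(x$distinct_mf_per_goc), "\n")
  cat("  GLOs per GOC axon:       ", f3(x$glo_per_goc_axon), "\n")
  cat("  inhibitory in-degree/GRC:", f3(x$inh_in_degree_grc), "\n")
  cat("  aa sources per GOC:      ", f3(x$aa_per_goc), "\n")
  cat("  pf sources per GOC:      ", f3(x$pf_per_goc), "\n")
  cat(sprintf("  delays (ms):              %.4g - %.4g\n",
              x$delay_range[1], x$delay_range[2]))
  invisible(x)
}

#' @export
print.gl_network <- function(x, ...) {
  cat(sprintf("gl_network: %g x %g x %g um^3, seed %s\n",
              x$volume$x, x$volume$y, x$volume$z, format(x$seed)))
  print(x$audit)
  invisible(x)
}
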