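#' Configuration for the synthetic coastal world
#'
#' The generator plants embayments of known class along a straight
#' macro-coast in a planar equal-area frame (km): protruding deltaic fans
#' dissected by distributary channels, funnel-shaped estuaries fed by one
#' trunk river, shore-parallel lagoons behind a barrier with a narrow
#' inlet, and simple semicircular bays. Mangrove units fringe every
#' embayment (plus open-coast strips), and gridded tide, suspended
#' particulate matter (SPM), monthly precipitation and above-ground biomass
#' (AGB) fields are laid over the scene. Default loss rates and AGB
#' parameters are the per-type values the global study reports, used here
#' as planted effect sizes.
#'
#' @param n_delta,n_estuary,n_lagoon,n_bay embayment counts per class.
#' @param cellsize_km raster cell size (km); the working resolution of all
#'   masks and rasters.
#' @param spacing_km along-coast distance between embayment centres.
#' @param bay_radius range (km) of the semicircular bay radius.
#' @param estuary_mouth_halfwidth,estuary_length funnel geometry ranges (km).
#' @param lagoon_length,lagoon_width lagoon basin ranges (km).
#' @param lagoon_inlet_width,lagoon_offset inlet width and barrier width (km).
#' @param delta_height fan protrusion range (km).
#' @param delta_distributaries distributary channel count per delta (> 2).
#' @param delta_channel_width carved channel width (km).
#' @param closing_radius_km coastline generalization radius.
#' @param min_cep_area_km2,min_landmass_km2,max_mangrove_dist_km embayment
#'   filter defaults.
#' @param fringe_km mangrove fringe width around embayments (km).
#' @param n_open_strips,strip_length,strip_fringe_km open-coast mangrove
#'   strip placement.
#' @param timesteps,timestep_years extent map labels and their years.
#' @param loss_rates named per-type fraction of baseline area lost over the
#'   whole period; names deltaic/estuarine/lagoonal/open_coast.
#' @param sediment_beta logit-scale (intercept, tide, SPM) coefficients of
#'   the terrigenous-versus-carbonate truth model (terrigenous = 1).
#' @param n_sites_riverine,n_sites_nonriverine sedimentary training sites.
#' @param agb_mean,agb_cv per-type mean AGB (Mg/ha) and cell-level
#'   lognormal coefficient of variation.
#' @param precip_base_mm,precip_amp monthly precipitation level and
#'   seasonal amplitude (seasonality = max/mean = 1 + amp).
#' @return A validated list of class `scene_config`.
#' @export
scene_config <- function(n_delta = 3L, n_estuary = 3L, n_lagoon = 3L,
                         n_bay = 3L,
                         cellsize_km = 0.5,
                         spacing_km = 24,
                         bay_radius = c(4, 7),
                         estuary_mouth_halfwidth = c(3, 5),
                         estuary_length = c(10, 16),
                         lagoon_length = c(8, 14),
                         lagoon_width = c(1.5, 2.5),
                         lagoon_inlet_width = 0.9,
                         lagoon_offset = 1.5,
                         delta_height = c(6, 8),
                         delta_distributaries = 4L,
                         delta_channel_width = 1.4,
                         closing_radius_km = 10,
                         min_cep_area_km2 = 1,
                         min_landmass_km2 = 30,
                         max_mangrove_dist_km = 20,
                         fringe_km = 1.5,
                         n_open_strips = 3L,
                         strip_length = c(10, 18),
                         strip_fringe_km = 1.0,
                         timesteps = c("1996", "2007", "2010", "2016"),
                         timestep_years = c(1996, 2007, 2010, 2016),
                         loss_rates = c(deltaic = 0.043, estuarine = 0.031,
                                        lagoonal = 0.069, open_coast = 0.043),
                         sediment_beta = c(-6, 3.0, 0.08),
                         n_sites_riverine = 70L,
                         n_sites_nonriverine = 82L,
                         agb_mean = c(deltaic = 117.3, estuarine = 126.3,
                                      lagoonal = 73.5, open_coast = 111.5),
                         agb_cv = 0.15,
                         precip_base_mm = 150,
                         precip_amp = 0.8) {
  counts <- c(n_delta, n_estuary, n_lagoon, n_bay)
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("configuration error: embayment counts must be nonnegative integers")
  if (cellsize_km <= 0)
    stop("configuration error: cellsize_km must be > 0")
  if (any(loss_rates < 0) || any(loss_rates > 1))
    stop("configuration error: loss_rates must lie in [0, 1]")
  if (delta_distributaries < 3)
    stop("configuration error: deltas need more than two distributaries")
  cfg <- as.list(environment())
  cfg$counts <- NULL
  class(cfg) <- "scene_config"
  cfg
}

geomorphic_type_of <- function(embayment_class) {
  c(delta = "deltaic", estuary = "estuarine",
    lagoon = "lagoonal", bay = "open_coast")[embayment_class]
}

# temporarily set the RNG, restoring the caller's stream
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  code
}

# distance from points to a segment a-b (vectorized over points)
seg_dist <- function(px, py, a, b) {
  vx <- b[1L] - a[1L]; vy <- b[2L] - a[2L]
  L2 <- vx^2 + vy^2
  if (L2 == 0) return(sqrt((px - a[1L])^2 + (py - a[2L])^2))
  t <- pmin(1, pmax(0, ((px - a[1L]) * vx + (py - a[2L]) * vy) / L2))
  sqrt((px - a[1L] - t * vx)^2 + (py - a[2L] - t * vy)^2)
}

#' Generate a synthetic coastal scene with known ground truth
#'
#' Deterministic under `(config, seed)`. Returns a `coast_scene` holding
#' the land mask, coastline polygons, river flowlines with downstream
#' pointers and outlet points, watershed polygons, environmental rasters,
#' mangrove extents per timestep, and the planted truth (embayment classes,
#' unit types, sedimentary labels, AGB means, loss rates).
#'
#' @param config a [scene_config()].
#' @param seed integer RNG seed.
#' @return Object of class `coast_scene`.
#' @export
generate_scene <- function(config = scene_config(), seed = 1L) {
  if (!inherits(config, "scene_config")) stop("configuration error: need a scene_config")
  with_seed(seed, generate_scene_impl(config, seed))
}

generate_scene_impl <- function(cfg, seed) {
  cs <- cfg$cellsize_km
  n_emb <- cfg$n_delta + cfg$n_estuary + cfg$n_lagoon + cfg$n_bay
  margin <- 16
  width <- max(2 * margin + cfg$spacing_km * max(n_emb - 1L, 0L), 60)
  height <- 120
  coast_y <- 60
  grid <- mt_grid(nrow = round(height / cs), ncol = round(width / cs),
                  xll = 0, yll = 0, cellsize = cs)
  idx_all <- seq_len(grid$nrow * grid$ncol)
  XY <- grid_cell_xy(grid, idx_all)
  X <- matrix(XY[, 1L], grid$nrow, grid$ncol)
  Y <- matrix(XY[, 2L], grid$nrow, grid$ncol)

  land <- Y >= coast_y
  emb_mask <- matrix(0L, grid$nrow, grid$ncol)

  classes <- rep(c("delta", "estuary", "lagoon", "bay"),
                 c(cfg$n_delta, cfg$n_estuary, cfg$n_lagoon, cfg$n_bay))
  emb <- NULL
  flow_geom <- list(); flow_attr <- NULL
  ws_geom <- list(); ws_attr <- NULL
  if (n_emb > 0L) {
    slots <- margin + cfg$spacing_km * seq(0L, n_emb - 1L)
    slots <- slots + stats::runif(n_emb, -2, 2)
    # shuffle classes along the coast, avoiding adjacent delta fans (their
    # shared valley would read as a spurious embayment)
    for (try in 1:100) {
      ord <- sample.int(n_emb)
      isd <- classes[ord] == "delta"
      if (n_emb < 2L || !any(isd[-1L] & isd[-n_emb])) break
    }
    classes <- classes[ord]
    emb <- data.frame(id = seq_len(n_emb), class = classes, xc = slots,
                      n_outlets = 0L, stringsAsFactors = FALSE)
    next_fl <- 1L; next_ws <- 1L
    runif1 <- function(r) stats::runif(1, r[1L], r[2L])
    add_flowline <- function(geom, downstream, outlet) {
      id <- next_fl; next_fl <<- next_fl + 1L
      flow_geom[[id]] <<- geom
      flow_attr <<- rbind(flow_attr, data.frame(
        id = id, downstream_id = downstream,
        outlet_x = if (is.null(outlet)) NA_real_ else outlet[1L],
        outlet_y = if (is.null(outlet)) NA_real_ else outlet[2L]))
      id
    }
    add_watershed <- function(rect, flowline_id) {
      id <- next_ws; next_ws <<- next_ws + 1L
      ring <- cbind(c(rect[1L], rect[2L], rect[2L], rect[1L]),
                    c(rect[3L], rect[3L], rect[4L], rect[4L]))
      ws_geom[[id]] <<- list(list(ring))
      ws_attr <<- rbind(ws_attr, data.frame(ws_id = id, flowline_id = flowline_id))
      id
    }
    # one or two chained upstream segments feeding `into_id` at point p
    add_upstream_chain <- function(into_id, p, n_up) {
      prev <- into_id; top <- p[2L]
      for (u in seq_len(n_up)) {
        q <- c(p[1L] + stats::runif(1, -3, 3), min(top + 14, height - 2))
        fid <- add_flowline(rbind(q, c(p[1L], top)), downstream = prev, outlet = NULL)
        add_watershed(c(p[1L] - 6, p[1L] + 6, top, q[2L]), fid)
        prev <- fid; top <- q[2L]
        if (top >= height - 4) break
      }
    }

    for (e in seq_len(n_emb)) {
      xc <- emb$xc[e]
      if (emb$class[e] == "bay") {
        r <- runif1(cfg$bay_radius)
        bite <- land & ((X - xc)^2 + (Y - coast_y)^2 <= r^2)
        land[bite] <- FALSE
        emb_mask[bite] <- e
      } else if (emb$class[e] == "estuary") {
        w0 <- runif1(cfg$estuary_mouth_halfwidth)
        L <- runif1(cfg$estuary_length)
        frac <- (Y - coast_y) / L
        hw <- w0 + (0.5 - w0) * frac
        funnel <- land & frac >= 0 & frac <= 1 & abs(X - xc) <= hw
        land[funnel] <- FALSE
        emb_mask[funnel] <- e
        head_pt <- c(xc, coast_y + L - 1)
        fid <- add_flowline(rbind(c(xc, coast_y + L + 14), head_pt),
                            downstream = NA_integer_, outlet = head_pt)
        add_watershed(c(xc - 7, xc + 7, coast_y + L, coast_y + L + 14), fid)
        add_upstream_chain(fid, c(xc, coast_y + L + 14),
                           n_up = sample(1:2, 1L))
        emb$n_outlets[e] <- 1L
      } else if (emb$class[e] == "lagoon") {
        Ll <- runif1(cfg$lagoon_length); Wl <- runif1(cfg$lagoon_width)
        off <- cfg$lagoon_offset; iw <- cfg$lagoon_inlet_width
        basin <- land & abs(X - xc) <= Ll / 2 &
          Y >= coast_y + off & Y <= coast_y + off + Wl
        inlet <- land & abs(X - xc) <= iw / 2 &
          Y >= coast_y & Y <= coast_y + off
        land[basin | inlet] <- FALSE
        emb_mask[basin | inlet] <- e
      } else { # delta
        h <- runif1(cfg$delta_height)
        sig <- h          # gentle flanks: closing pockets stay sub-cell
        profile_y <- function(x) coast_y - h * exp(-((x - xc) / sig)^2)
        prof <- profile_y(X)
        fan <- !land & Y < coast_y & Y >= prof & abs(X - xc) <= 2 * sig
        land[fan] <- TRUE
        k <- cfg$delta_distributaries
        wch <- cfg$delta_channel_width
        B <- c(xc, coast_y - 0.35 * h)
        A <- c(xc, coast_y + 3)
        channel <- seg_dist(X, Y, A, B) <= wch / 2
        outlets <- matrix(NA_real_, k, 2L)
        u <- seq(-0.9, 0.9, length.out = k)
        dist_ids <- integer(k)
        for (q in seq_len(k)) {
          ex <- xc + u[q] * sig
          prof_y <- profile_y(ex)
          E <- c(ex, prof_y - 1.5)   # channel runs clear of the fan edge
          channel <- channel | (seg_dist(X, Y, B, E) <= wch / 2)
          # outlet: where the distributary centreline crosses the fan edge
          # (the drainage outlet to the ocean), nudged just inside
          tt <- seq(0, 1, length.out = 200)
          px <- B[1L] + tt * (E[1L] - B[1L])
          py <- B[2L] + tt * (E[2L] - B[2L])
          inside <- py >= profile_y(px)
          cross <- if (any(inside)) max(which(inside)) else 1L
          outlets[q, ] <- c(px[cross], py[cross] + 0.25)
        }
        carved <- land & channel
        land[carved] <- FALSE
        emb_mask[carved] <- e
        trunk <- add_flowline(rbind(c(xc, coast_y + 16), B),
                              downstream = NA_integer_, outlet = NULL)
        add_watershed(c(xc - 7, xc + 7, coast_y + 3, coast_y + 16), trunk)
        add_upstream_chain(trunk, c(xc, coast_y + 16), n_up = sample(1:2, 1L))
        for (q in seq_len(k)) {
          dist_ids[q] <- add_flowline(rbind(B, outlets[q, ]),
                                      downstream = NA_integer_,
                                      outlet = outlets[q, ])
        }
        # canonical single downstream pointer for the braided split
        flow_attr$downstream_id[flow_attr$id == trunk] <- dist_ids[1L]
        emb$n_outlets[e] <- k
      }
    }
  }

  flowlines <- vector_layer(flow_geom,
                            if (is.null(flow_attr)) data.frame() else flow_attr,
                            "polyline")
  watersheds <- vector_layer(ws_geom,
                             if (is.null(ws_attr)) data.frame() else ws_attr,
                             "polygon")

  # ---- mangrove units: fringe of land around each embayment -------------
  unit_mask <- matrix(0L, grid$nrow, grid$ncol)
  units <- data.frame(unit_id = integer(0), class = character(0),
                      emb_id = integer(0), stringsAsFactors = FALSE)
  if (n_emb > 0L) {
    alloc <- allocate_nearest(emb_mask)
    dmang <- distance_transform(emb_mask > 0L, cs)
    fr <- land & dmang <= cfg$fringe_km
    unit_mask[fr] <- alloc[fr]
    for (e in seq_len(n_emb)) {
      if (!any(unit_mask == e)) next
      units <- rbind(units, data.frame(
        unit_id = e, class = unname(geomorphic_type_of(emb$class[e])),
        emb_id = e, stringsAsFactors = FALSE))
    }
  }
  # open-coast strips in embayment-free stretches of the straight coast
  if (cfg$n_open_strips > 0L) {
    occupied <- if (n_emb > 0L) sort(emb$xc) else numeric(0)
    gaps <- cbind(c(0, occupied + 11), c(occupied - 11, width))
    gaps <- gaps[gaps[, 2L] - gaps[, 1L] >= max(cfg$strip_length) + 2, ,
                 drop = FALSE]
    ns <- min(cfg$n_open_strips, nrow(gaps))
    gsel <- if (nrow(gaps)) sample.int(nrow(gaps), ns) else integer(0)
    for (s in seq_len(ns)) {
      g0 <- gaps[gsel[s], ]
      len <- stats::runif(1, cfg$strip_length[1L],
                          min(cfg$strip_length[2L], g0[2L] - g0[1L] - 2))
      x0 <- stats::runif(1, g0[1L] + 1, g0[2L] - 1 - len)
      strip <- land & X >= x0 & X <= x0 + len &
        Y >= coast_y & Y <= coast_y + cfg$strip_fringe_km & unit_mask == 0L
      if (!any(strip)) next
      uid <- n_emb + s
      unit_mask[strip] <- uid
      units <- rbind(units, data.frame(unit_id = uid, class = "open_coast",
                                       emb_id = NA_integer_,
                                       stringsAsFactors = FALSE))
    }
  }

  # ---- precipitation (12 monthly bands, mm) -----------------------------
  precip <- array(0, c(grid$nrow, grid$ncol, 12L))
  base <- cfg$precip_base_mm * (1 + 0.3 * sin(X / 50))
  for (m in 1:12)
    precip[, , m] <- base * (1 + cfg$precip_amp * cos(2 * pi * (m - 1) / 12))
  precip_rf <- raster_field(precip, grid, nodata = -9999, units = "mm/month")

  scene <- structure(list(
    grid = grid, land = land, coast_y = coast_y,
    coastline = vector_layer(trace_mask(land, grid) |> list(),
                             data.frame(name = "land"), "polygon"),
    flowlines = flowlines, watersheds = watersheds,
    precip = precip_rf, tide = NULL, spm = NULL, agb = NULL,
    extents = NULL,
    truth = list(embayments = if (is.null(emb)) data.frame(
                   id = integer(0), class = character(0), xc = numeric(0),
                   n_outlets = integer(0)) else emb,
                 emb_mask = emb_mask,
                 units = units, unit_mask = unit_mask,
                 loss_rates = cfg$loss_rates, beta = cfg$sediment_beta,
                 agb_mean = cfg$agb_mean),
    sites = NULL, config = cfg, seed = seed), class = "coast_scene")

  scene <- generate_sediment_fields(scene, cfg$sediment_beta,
                                    seed = seed + 1000L)
  scene <- generate_agb_field(scene, seed = seed + 2000L)
  scene <- generate_timesteps(scene, cfg$loss_rates, seed = seed + 3000L)
  scene
}

#' Tide and SPM fields, sedimentary truth and training sites
#'
#' Lays smooth, strictly positive M2 tidal-amplitude (m) and mean inorganic
#' SPM (g m^-3, 12 monthly bands) fields over the scene, draws each
#' lagoonal / open-coast unit's terrigenous-versus-carbonate truth as
#' Bernoulli with probability `plogis(beta %*% c(1, tide, spm))` at the
#' unit centroid (deltaic and estuarine units are terrigenous by
#' definition), and places labelled training sites within 10 km of the
#' mangrove extent.
#'
#' @param scene a `coast_scene`.
#' @param beta logit-scale (intercept, tide, SPM) coefficients,
#'   terrigenous = 1 coding.
#' @param seed integer seed.
#' @return the scene with `tide`, `spm`, unit sediment truth and `sites`.
#' @export
generate_sediment_fields <- function(scene, beta = scene$config$sediment_beta,
                                     seed = 1L) {
  with_seed(seed, {
    grid <- scene$grid
    idx_all <- seq_len(grid$nrow * grid$ncol)
    XY <- grid_cell_xy(grid, idx_all)
    X <- matrix(XY[, 1L], grid$nrow, grid$ncol)
    Y <- matrix(XY[, 2L], grid$nrow, grid$ncol)
    width <- grid$ncol * grid$cellsize
    tide <- 0.4 + 2.8 * stats::plogis((X - width / 2) / 8) +
      0.1 * sin(Y / 17)
    tide[tide < 0.05] <- 0.05
    spm <- array(0, c(grid$nrow, grid$ncol, 12L))
    spm_base <- 4 + 2 * exp(-((X - width * 0.65) / (0.3 * width))^2) +
      0.4 * sin(X / 13)
    for (m in 1:12)
      spm[, , m] <- spm_base * (1 + 0.25 * cos(2 * pi * (m - 2) / 12))
    scene$tide <- raster_field(tide, grid, units = "m")
    scene$spm <- raster_field(spm, grid, units = "g/m3")

    units <- scene$truth$units
    if (nrow(units)) {
      sed <- character(nrow(units)); p_terr <- numeric(nrow(units))
      spm_mean <- apply(spm, c(1, 2), mean)
      for (r in seq_len(nrow(units))) {
        cells <- which(scene$truth$unit_mask == units$unit_id[r])
        ctr <- colMeans(grid_cell_xy(grid, cells))
        rc <- grid_xy_cell(grid, ctr[1L], ctr[2L])
        tv <- tide[rc[1L], rc[2L]]; sv <- spm_mean[rc[1L], rc[2L]]
        p <- stats::plogis(beta[1L] + beta[2L] * tv + beta[3L] * sv)
        p_terr[r] <- p
        sed[r] <- if (units$class[r] %in% c("deltaic", "estuarine"))
          "terrigenous"
        else if (stats::rbinom(1L, 1L, p) == 1L) "terrigenous" else "carbonate"
      }
      units$sediment <- sed
      units$p_terrigenous <- p_terr
      scene$truth$units <- units
    }

    # training sites on mangrove cells (hence within 10 km of the extent)
    cfg <- scene$config
    site_rows <- list()
    pick_sites <- function(n, unit_classes, status) {
      pool <- which(scene$truth$unit_mask %in%
                      units$unit_id[units$class %in% unit_classes])
      if (length(pool) == 0L || n == 0L) return(NULL)
      cells <- pool[sample.int(length(pool), n, replace = length(pool) < n)]
      xy <- grid_cell_xy(grid, cells)
      data.frame(x = xy[, 1L] + stats::runif(n, -0.2, 0.2),
                 y = xy[, 2L] + stats::runif(n, -0.2, 0.2),
                 typological_status = status, stringsAsFactors = FALSE)
    }
    if (nrow(units)) {
      site_rows$riv <- pick_sites(cfg$n_sites_riverine,
                                  c("deltaic", "estuarine"), "riverine")
      site_rows$non <- pick_sites(cfg$n_sites_nonriverine,
                                  c("lagoonal", "open_coast"), "non_riverine")
    }
    sites <- do.call(rbind, site_rows)
    if (!is.null(sites) && nrow(sites)) {
      spm_mean <- apply(spm, c(1, 2), mean)
      rc <- grid_xy_cell(grid, sites$x, sites$y)
      tv <- tide[rc]; sv <- spm_mean[rc]
      p <- stats::plogis(beta[1L] + beta[2L] * tv + beta[3L] * sv)
      lab <- ifelse(stats::rbinom(nrow(sites), 1L, p) == 1L,
                    "terrigenous", "carbonate")
      # riverine sites sit in river-fed settings: terrigenous by definition
      lab[sites$typological_status == "riverine"] <- "terrigenous"
      sites <- data.frame(site_id = seq_len(nrow(sites)), sites,
                          sediment_label = lab, stringsAsFactors = FALSE)
      rownames(sites) <- NULL
    }
    scene$sites <- sites
    scene
  })
}

# AGB raster: lognormal cell noise around the planted per-type mean,
# defined on mangrove cells only (nodata elsewhere)
generate_agb_field <- function(scene, seed = 1L) {
  with_seed(seed, {
    grid <- scene$grid
    agb <- matrix(-9999, grid$nrow, grid$ncol)
    units <- scene$truth$units
    cv <- scene$config$agb_cv
    sdl <- sqrt(log(1 + cv^2))
    for (r in seq_len(nrow(units))) {
      cells <- which(scene$truth$unit_mask == units$unit_id[r])
      m <- scene$config$agb_mean[[units$class[r]]]
      agb[cells] <- m * exp(stats::rnorm(length(cells), -sdl^2 / 2, sdl))
    }
    scene$agb <- raster_field(agb, grid, nodata = -9999, units = "Mg/ha")
    scene
  })
}

#' Erode mangrove extents through time at planted per-type rates
#'
#' The first timestep is the full baseline (the union of all planted unit
#' cells). For each unit, `round(rate * n_cells)` cells are removed by the
#' final timestep, in a fixed random order, with the cumulative removed
#' count at an intermediate timestep proportional to elapsed years. Later
#' extents are therefore nested subsets of the baseline and the realized
#' per-type loss matches the requested rate to within one raster cell per
#' unit.
#'
#' @param scene a `coast_scene`.
#' @param loss_rate named per-type fractions in \[0, 1\]
#'   (deltaic/estuarine/lagoonal/open_coast).
#' @param seed integer seed.
#' @return the scene with `extents` set (named list of logical masks).
#' @export
generate_timesteps <- function(scene, loss_rate = scene$config$loss_rates,
                               seed = 1L) {
  if (any(loss_rate < 0) || any(loss_rate > 1))
    stop("loss_rate must lie in [0, 1]")
  with_seed(seed, {
    cfg <- scene$config
    years <- cfg$timestep_years
    frac <- (years - years[1L]) / max(years[length(years)] - years[1L], 1)
    base <- scene$truth$unit_mask > 0L
    extents <- stats::setNames(rep(list(base), length(cfg$timesteps)),
                               cfg$timesteps)
    units <- scene$truth$units
    for (r in seq_len(nrow(units))) {
      cells <- which(scene$truth$unit_mask == units$unit_id[r])
      rate <- loss_rate[[units$class[r]]]
      total_rm <- round(rate * length(cells))
      if (total_rm == 0L) next
      order_rm <- cells[sample.int(length(cells))]
      for (t in seq_along(extents)) {
        k <- round(total_rm * frac[t])
        if (k > 0L) extents[[t]][order_rm[seq_len(k)]] <- FALSE
      }
    }
    scene$extents <- extents
    scene
  })
}

#' @export
print.coast_scene <- function(x, ...) {
  cat("<coast_scene> ", x$grid$nrow, "x", x$grid$ncol, " cells @ ",
      x$grid$cellsize, " km\n", sep = "")
  cat("  embayments: ", nrow(x$truth$embayments),
      " | mangrove units: ", nrow(x$truth$units),
      " | timesteps: ", paste(names(x$extents), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Serialize a scene to plain-text files
#'
#' Writes the vector layers as GeoJSON, the rasters as (multi-band) ASCII
#' grids, the extents as one ASCII grid per timestep, and the truth tables
#' as CSV into `dir`.
#'
#' @param scene a `coast_scene`.
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of files written.
#' @export
write_scene <- function(scene, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  wv <- function(layer, name) {
    p <- file.path(dir, paste0(name, ".geojson")); write_vector(layer, p); p
  }
  wr <- function(field, name) {
    p <- file.path(dir, paste0(name, ".asc")); write_raster(field, p); p
  }
  files <- c(files, wv(scene$coastline, "coastline"),
             wv(scene$flowlines, "flowlines"),
             wv(scene$watersheds, "watersheds"),
             wr(scene$precip, "precip"), wr(scene$tide, "tide"),
             wr(scene$spm, "spm"), wr(scene$agb, "agb"))
  for (ts in names(scene$extents)) {
    f <- raster_field(scene$extents[[ts]] * 1, scene$grid, nodata = -9999)
    files <- c(files, wr(f, paste0("extent_", ts)))
  }
  p <- file.path(dir, "truth_embayments.csv")
  utils::write.csv(scene$truth$embayments[, c("id", "class")], p,
                   row.names = FALSE)
  files <- c(files, p)
  p <- file.path(dir, "truth_units.csv")
  utils::write.csv(scene$truth$units, p, row.names = FALSE)
  files <- c(files, p)
  if (!is.null(scene$sites)) {
    p <- file.path(dir, "sediment_sites.csv")
    utils::write.csv(scene$sites, p, row.names = FALSE)
    files <- c(files, p)
  }
  invisible(files)
}
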