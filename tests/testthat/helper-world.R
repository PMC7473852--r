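# Shared fixtures, built once per run and cached. Everything is generated
# in code from the default synthetic world (seed 1) or small hand
# constructions; nothing is read from disk.

.cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (is.null(.cache[[key]])) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

world_scene <- function() cached("scene", generate_scene(scene_config(), seed = 1))
world_processed <- function() cached("proc", process_scene(world_scene()))
world_training <- function() cached(
  "train", training_covariates(2, scene_config(), seed = 900))
world_rf <- function() cached("rf", train_rf(world_training(), n_trees = 300,
                                             seed = 1))
world_pipeline <- function() cached(
  "pipe", suppressWarnings(suppressMessages(
    run_pipeline(scene_config(), seed = 1, n_trees = 300))))

# regular n-gon ring of radius r (approximates a circle for closed forms)
circle_ring <- function(r = 1, n = 512, cx = 0, cy = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}

rect_ring <- function(x0, y0, w, h) {
  cbind(c(x0, x0 + w, x0 + w, x0), c(y0, y0, y0 + h, y0 + h))
}

# straight-coast land mask world (land in the upper half), for hand builds
flat_world <- function(nr = 60, nc = 80, cs = 0.5, coast_frac = 0.5) {
  g <- mt_grid(nr, nc, 0, 0, cs)
  xy <- mangrovetyper:::grid_cell_xy(g, seq_len(nr * nc))
  list(grid = g,
       X = matrix(xy[, 1], nr, nc), Y = matrix(xy[, 2], nr, nc),
       coast_y = nr * cs * coast_frac)
}
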