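# print-style rounding (half away from zero), matching how the source
# tables print percentages; R's round() is half-even
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  trunc(x * m + sign(x) * 0.5) / m
}

#' Tabulate unit areas by region, type and timestep
#'
#' Long-format change table: one row per (region, type, [sediment],
#' timestep) with the summed area in km^2. Regions present in the region
#' vocabulary but holding no mangrove appear as zero rows.
#'
#' @param units a `typology_units` object, or a data.frame with `type`,
#'   `region`, optional `sediment`, and `area_<timestep>` columns.
#' @param timesteps timestep labels; default from the units object /
#'   `area_` columns.
#' @param regions optional character vector fixing the region vocabulary.
#' @return data.frame of class `change_table` (region, type, [sediment],
#'   timestep, km2).
#' @export
tabulate_areas <- function(units, timesteps = NULL, regions = NULL) {
  tab <- if (inherits(units, "typology_units")) units$table else units
  if (is.null(timesteps)) {
    ac <- grep("^area_", colnames(tab), value = TRUE)
    timesteps <- sub("^area_", "", ac)
  }
  miss <- setdiff(paste0("area_", timesteps), colnames(tab))
  if (length(miss))
    stop("unit ", tab$unit_id[1L], " missing timestep area column ", miss[1L])
  tab$region <- if (is.null(tab$region)) "all" else
    ifelse(is.na(tab$region), "all", tab$region)
  has_sed <- !is.null(tab$sediment)
  keys <- c("region", "type", if (has_sed) "sediment")
  rows <- list()
  for (tsn in timesteps) {
    ag <- stats::aggregate(tab[[paste0("area_", tsn)]],
                           by = tab[keys], FUN = sum)
    names(ag)[ncol(ag)] <- "km2"
    ag$timestep <- tsn
    rows[[tsn]] <- ag
  }
  out <- do.call(rbind, rows)
  if (!is.null(regions)) {
    types <- unique(out$type)
    for (r in setdiff(regions, unique(out$region)))
      for (ty in types)
        for (tsn in timesteps) {
          zr <- out[1L, , drop = FALSE]
          zr$region <- r; zr$type <- ty; zr$timestep <- tsn; zr$km2 <- 0
          if (has_sed) zr$sediment <- NA_character_
          out <- rbind(out, zr)
        }
  }
  rownames(out) <- NULL
  out <- out[, c(keys, "timestep", "km2")]
  class(out) <- c("change_table", "data.frame")
  out
}

#' Per-type shares of total mangrove area at a timestep
#'
#' 100 * type total / global total, printed to one decimal (half-up); the
#' raw unrounded shares ride along as the `"raw"` attribute.
#'
#' @param table a `change_table` (or compatible long data.frame).
#' @param timestep timestep label.
#' @return named numeric vector of percentages by type.
#' @export
type_shares <- function(table, timestep) {
  sub <- table[table$timestep == timestep, , drop = FALSE]
  if (nrow(sub) == 0L) stop("timestep ", timestep, " not present")
  tot <- sum(sub$km2)
  if (tot <= 0) stop("undefined share: zero global total at ", timestep)
  by_type <- tapply(sub$km2, sub$type, sum)
  raw <- stats::setNames(as.numeric(100 * by_type / tot), names(by_type))
  out <- round_half_up(raw, 1)
  attr(out, "raw") <- raw
  out
}

#' Percent change in area between two timesteps
#'
#' `100 * (A(t1) - A(t0)) / A(t0)` per group, one decimal (half-up).
#' Groups absent at `t0` are reported NA; identical timesteps return zeros
#' with a warning.
#'
#' @param table a `change_table`.
#' @param t0,t1 timestep labels.
#' @param grouping `"type"`, `"region"`, `"sediment"` or `"global"`.
#' @return named numeric vector of percent changes (attribute `"raw"`
#'   carries unrounded values).
#' @export
percent_change <- function(table, t0, t1,
                           grouping = c("type", "region", "sediment",
                                        "global")) {
  grouping <- match.arg(grouping)
  if (identical(t0, t1)) {
    warning("t0 and t1 identical; returning zeros")
  }
  for (ts in c(t0, t1))
    if (!any(table$timestep == ts)) stop("timestep ", ts, " not present")
  sum_by <- function(ts) {
    sub <- table[table$timestep == ts, , drop = FALSE]
    if (grouping == "global") return(c(global = sum(sub$km2)))
    if (is.null(sub[[grouping]]))
      stop("table has no '", grouping, "' column")
    tapply(sub$km2, sub[[grouping]], sum)
  }
  a0 <- sum_by(t0); a1 <- sum_by(t1)
  groups <- union(names(a0), names(a1))
  raw <- vapply(groups, function(g) {
    v0 <- if (g %in% names(a0)) a0[[g]] else 0
    v1 <- if (g %in% names(a1)) a1[[g]] else 0
    if (v0 == 0) NA_real_ else 100 * (v1 - v0) / v0
  }, numeric(1))
  out <- round_half_up(raw, 1)
  attr(out, "raw") <- raw
  out
}

#' Rank units by net area loss
#'
#' Descending by `A(t0) - A(t1)`; ties break by unit id.
#'
#' @param units `typology_units` or a data.frame with `unit_id`, `type`
#'   and `area_<t>` columns.
#' @param t0,t1 timestep labels.
#' @param top_n rows to return (0 gives an empty table).
#' @return data.frame (unit_id, type, loss_km2) sorted by loss.
#' @export
rank_losses <- function(units, t0, t1, top_n = 10L) {
  tab <- if (inherits(units, "typology_units")) units$table else units
  loss <- tab[[paste0("area_", t0)]] - tab[[paste0("area_", t1)]]
  ord <- order(-loss, tab$unit_id)
  out <- data.frame(unit_id = tab$unit_id[ord], type = tab$type[ord],
                    loss_km2 = loss[ord], stringsAsFactors = FALSE)
  utils::head(out, max(0L, top_n))
}

#' Load a printed area table shipped with the package
#'
#' Reads a wide CSV (`region`, one column per type, km^2) into the long
#' `change_table` layout, tagged with one timestep. The package ships the
#' published 2016 regional area table and the printed global extent
#' figures as plain-text fixtures under `extdata/`.
#'
#' @param path CSV path; default the shipped 2016 regional table.
#' @param timestep label attached to the rows.
#' @return a `change_table`.
#' @export
read_area_table <- function(path = system.file("extdata",
                                               "area_2016_by_region_type.csv",
                                               package = "mangrovetyper"),
                            timestep = "2016") {
  wide <- utils::read.csv(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  types <- setdiff(colnames(wide), "region")
  out <- do.call(rbind, lapply(types, function(ty)
    data.frame(region = wide$region, type = ty, timestep = timestep,
               km2 = wide[[ty]], stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  class(out) <- c("change_table", "data.frame")
  out
}
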