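# Visual mucus scoring over an extended monopodial murine airway
# nomenclature: 11 generations across the five lung lobes (RUL, RML, RLL,
# RCL, LL), the trachea (generation 0) excluded by design.  Scores are
# ordinal: 0 = no mucus, 1 = mucus obstructing up to 50 % of the lumen,
# 2 = more than 50 %.

#' Construct the monopodial nomenclature catalog
#'
#' Each lobe carries an axial trunk of generations 1-11; lateral daughters
#' bud off trunk generations 2-9 and extend up to three further generations
#' (monopodial architecture).  Successive depth levels in segment labels use
#' capital letters (trunk generation), lowercase letters and Roman numerals,
#' e.g. `RUL-C`, `RUL-Ca`, `RUL-CaI`.  The exact inventory below the trunk
#' is an artifact construction (the published nomenclature figure is not
#' machine-readable); the catalog is plain data so users can substitute
#' their own via CSV.
#'
#' @param max_generation deepest generation (default 11).
#' @return data.table `segment_label, lobe, generation, parent`.
#' @export
make_monopodial_catalog <- function(max_generation = 11L) {
  roman <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII", "IX", "X", "XI")
  rows <- list()
  for (lobe in LOBE_CODES) {
    trunk <- paste0(lobe, "-", LETTERS[seq_len(max_generation)])
    for (g in seq_len(max_generation)) {
      rows[[length(rows) + 1L]] <- data.table(
        segment_label = trunk[g], lobe = lobe, generation = g,
        parent = if (g == 1L) NA_character_ else trunk[g - 1L])
    }
    for (g in 2:9) {
      depth <- min(3L, max_generation - g)
      if (depth < 1L) next
      lat <- paste0(trunk[g], "a")
      rows[[length(rows) + 1L]] <- data.table(
        segment_label = lat, lobe = lobe, generation = g + 1L, parent = trunk[g])
      prev <- lat
      for (d in seq_len(depth - 1L)) {
        nm <- paste0(lat, roman[d])
        rows[[length(rows) + 1L]] <- data.table(
          segment_label = nm, lobe = lobe, generation = g + 1L + d, parent = prev)
        prev <- nm
      }
    }
  }
  out <- rbindlist(rows)
  setorder(out, lobe, generation, segment_label)
  out[]
}

#' The packaged airway nomenclature catalog
#'
#' Reads the CSV shipped in `inst/extdata/airway_catalog.csv` (editable by
#' users); it spans generations 1-11 in all five lobes with a valid parent
#' chain and contains no trachea entry.
#'
#' @return data.table `segment_label, lobe, generation, parent`.
#' @export
default_catalog <- function() {
  path <- system.file("extdata", "airway_catalog.csv", package = "airwayplug")
  if (path == "") stop("packaged catalog not found")
  d <- as.data.table(read.csv(path, stringsAsFactors = FALSE))
  d$parent[d$parent == ""] <- NA_character_
  d[]
}

#' Ordinal mucus score from a mucus area ratio
#'
#' 0 for no mucus, 1 for obstruction up to 50 % of the lumen (inclusive),
#' 2 beyond 50 %.
#'
#' @param area_ratio fractions in `[0, 1]`.
#' @return integer scores in `{0, 1, 2}`.
#' @export
auto_score <- function(area_ratio) {
  if (any(is.na(area_ratio)) || any(area_ratio < -1e-9 | area_ratio > 1 + 1e-9))
    stop("area_ratio must be in [0, 1]")
  ifelse(area_ratio <= 1e-6, 0L, ifelse(area_ratio <= 0.5, 1L, 2L))
}

#' Aggregate segment scores to per-animal mean scores
#'
#' Means are taken over scored segments only; strata in which an animal has
#' no scored segment yield `NA`, never 0.
#'
#' @param table a validated score table ([read_score_csv()] or
#'   [generate_score_table()]).
#' @param by `"whole"` (whole organ), `"lobe"` or `"generation"`.
#' @return data.table with `animal_id, genotype, age_group`, the stratum
#'   column (unless `whole`) and `mean_score`.
#' @export
aggregate_scores <- function(table, by = c("whole", "lobe", "generation")) {
  by <- match.arg(by)
  t <- as.data.table(table)
  if (!nrow(t)) stop("empty score table")
  animals <- unique(t[, .(animal_id, genotype, age_group)])
  if (by == "whole") {
    out <- t[, .(mean_score = mean(score)), by = .(animal_id, genotype, age_group)]
  } else {
    strat <- if (by == "lobe") "lobe" else "generation"
    cat_dt <- attr(table, "catalog")
    strata <- if (!is.null(cat_dt)) sort(unique(cat_dt[[strat]])) else sort(unique(t[[strat]]))
    grid <- CJ(animal_id = animals$animal_id, stratum = strata)
    obs <- t[, .(mean_score = mean(score)), by = c("animal_id", strat)]
    setnames(obs, strat, "stratum")
    out <- merge(grid, obs, by = c("animal_id", "stratum"), all.x = TRUE)
    out <- merge(animals, out, by = "animal_id")
    setnames(out, "stratum", strat)
  }
  setorder(out, animal_id)
  out[]
}
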