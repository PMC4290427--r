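## Route-level communities: each survey site's species list is the union
## over all surveyed years, with abundance counts summed across years.
## A community_table is a named list of named count vectors plus optional
## site coordinates and a dataset-variant tag (FULL / NO_ALIENS / NO_RARE).

#' Filtering configuration for community assembly
#'
#' @param min_richness minimum species richness for a site to be kept
#'   (default 25: sites with fewer species are treated as under-sampled).
#' @param rare_fraction species contributing strictly less than this share
#'   of all individuals seen at a site are dropped by [remove_rare()]
#'   (default 0.01, i.e. the 1-percent rule with a strict `<` boundary).
#' @param aliens character vector of alien/invasive species labels.
#' @param synonyms named character vector mapping reported labels (e.g.
#'   sub-species) to the parent label used in the phylogeny.
#' @return a `filter_config` list.
#' @export
filter_config <- function(min_richness = 25L, rare_fraction = 0.01,
                          aliens = character(0), synonyms = character(0)) {
  min_richness <- as.integer(min_richness)
  if (min_richness < 2L) stop("min_richness must be >= 2", call. = FALSE)
  if (rare_fraction < 0 || rare_fraction >= 1)
    stop("rare_fraction must be in [0, 1)", call. = FALSE)
  if (length(synonyms) && is.null(names(synonyms)))
    stop("synonyms must be a named vector (from -> to)", call. = FALSE)
  structure(list(min_richness = min_richness, rare_fraction = rare_fraction,
                 aliens = as.character(aliens), synonyms = synonyms),
            class = "filter_config")
}

.new_community_table <- function(communities, coords = NULL,
                                 variant = "FULL") {
  structure(list(communities = communities, coords = coords,
                 variant = variant), class = "community_table")
}

#' @export
print.community_table <- function(x, ...) {
  rich <- community_richness(x)
  cat(sprintf("Community table [%s]: %d site(s), richness %s\n",
              x$variant, length(x$communities),
              if (length(rich)) paste0(min(rich), "-", max(rich)) else "-"))
  invisible(x)
}

#' Species richness per community
#'
#' @param table a `community_table`.
#' @return named integer vector of per-site species counts.
#' @export
community_richness <- function(table) {
  vapply(table$communities, length, integer(1))
}

#' Read survey records from CSV
#'
#' Expected columns: `site, species, count` and optionally `year`, `lat`,
#' `lon`.
#'
#' @param path CSV path.
#' @return data.frame of survey records.
#' @export
read_survey_records <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site", "species", "count")
  if (!all(need %in% names(rec)))
    stop("survey CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(rec$count < 0) || anyNA(rec$count))
    stop("counts must be non-negative and non-missing", call. = FALSE)
  if (any(!nzchar(rec$site)) || any(!nzchar(rec$species)))
    stop("site and species must be non-empty", call. = FALSE)
  rec
}

#' Collapse survey records across years into communities
#'
#' Per site, the community is the union of species over all years with
#' counts summed; coordinates, where present, must agree across a site's
#' records (within `coord_tol`).
#'
#' @param records data.frame as from [read_survey_records()].
#' @param coord_tol tolerance for coordinate agreement (default 1e-6
#'   degrees).
#' @return a `community_table` with variant `"FULL"`.
#' @export
collapse_years <- function(records, coord_tol = 1e-6) {
  if (nrow(records) == 0L) stop("no survey records", call. = FALSE)
  agg <- stats::aggregate(count ~ site + species, data = records, FUN = sum)
  agg <- agg[order(agg$site, agg$species), ]
  communities <- lapply(split(agg, agg$site), function(df)
    stats::setNames(df$count, df$species))
  coords <- NULL
  if (all(c("lat", "lon") %in% names(records))) {
    by_site <- split(records, records$site)
    coords <- do.call(rbind, lapply(names(by_site), function(s) {
      la <- unique(stats::na.omit(by_site[[s]]$lat))
      lo <- unique(stats::na.omit(by_site[[s]]$lon))
      if (length(la) > 1L && diff(range(la)) > coord_tol ||
          length(lo) > 1L && diff(range(lo)) > coord_tol)
        stop("conflicting coordinates for site ", s, call. = FALSE)
      data.frame(site = s, lat = if (length(la)) la[1L] else NA_real_,
                 lon = if (length(lo)) lo[1L] else NA_real_,
                 stringsAsFactors = FALSE)
    }))
    coords <- coords[match(names(communities), coords$site), ]
  }
  .new_community_table(communities, coords, variant = "FULL")
}

#' Drop under-sampled communities
#'
#' Removes sites whose species richness is below `cfg$min_richness`.
#'
#' @param table a `community_table`.
#' @param cfg a [filter_config()].
#' @return the filtered `community_table`.
#' @export
filter_min_richness <- function(table, cfg = filter_config()) {
  keep <- community_richness(table) >= cfg$min_richness
  if (any(!keep))
    message(sum(!keep), " site(s) dropped below richness ", cfg$min_richness)
  if (!any(keep))
    warning("no communities remain after richness filtering", call. = FALSE)
  table$communities <- table$communities[keep]
  if (!is.null(table$coords))
    table$coords <- table$coords[table$coords$site %in%
                                   names(table$communities), ]
  table
}

#' Remove alien species from all communities
#'
#' Produces the NO_ALIENS dataset variant; the richness filter is not
#' re-applied (the variant keeps the same set of sites).
#'
#' @inheritParams filter_min_richness
#' @return a `community_table` with variant `"NO_ALIENS"`.
#' @export
remove_aliens <- function(table, cfg) {
  table$communities <- lapply(table$communities, function(cm)
    cm[!(names(cm) %in% cfg$aliens)])
  table$variant <- "NO_ALIENS"
  table
}

#' Remove locally rare species from all communities
#'
#' Within each community, species whose count is strictly less than
#' `cfg$rare_fraction` of the site's total individuals are dropped
#' (the NO_RARE variant).
#'
#' @inheritParams filter_min_richness
#' @return a `community_table` with variant `"NO_RARE"`.
#' @export
remove_rare <- function(table, cfg = filter_config()) {
  nm <- names(table$communities)
  table$communities <- stats::setNames(lapply(nm, function(s) {
    cm <- table$communities[[s]]
    tot <- sum(cm)
    if (tot <= 0) stop("community ", s, " has zero total count",
                       call. = FALSE)
    cm[cm / tot >= cfg$rare_fraction]
  }), nm)
  table$variant <- "NO_RARE"
  table
}

#' Reconcile community species names against a reference label set
#'
#' Applies the synonym map first (e.g. sub-species substituted by their
#' parent species, counts merged), then drops and logs species absent from
#' `known` (e.g. not in the phylogeny).
#'
#' @param table a `community_table`.
#' @param known character vector of accepted labels (e.g. tree tips).
#' @param cfg a [filter_config()] carrying the synonym map.
#' @return the reconciled `community_table`.
#' @export
reconcile_names <- function(table, known, cfg = filter_config()) {
  if (length(known) == 0L) stop("'known' must be non-empty", call. = FALSE)
  syn <- cfg$synonyms
  if (length(syn)) {
    # reject cycles: following the map from any key must terminate
    for (k in names(syn)) {
      seen <- character(0); v <- k
      while (v %in% names(syn)) {
        if (v %in% seen) stop("synonym cycle involving '", k, "'",
                              call. = FALSE)
        seen <- c(seen, v); v <- unname(syn[[v]])
      }
    }
  }
  resolve <- function(lbl) {
    while (lbl %in% names(syn)) lbl <- unname(syn[[lbl]])
    lbl
  }
  dropped <- 0L
  table$communities <- lapply(table$communities, function(cm) {
    labs <- vapply(names(cm), resolve, character(1))
    merged <- tapply(cm, labs, sum)
    cm2 <- stats::setNames(as.numeric(merged), names(merged))
    bad <- !(names(cm2) %in% known)
    dropped <<- dropped + sum(bad)
    cm2[!bad]
  })
  if (dropped > 0L)
    message(dropped, " species record(s) not in the reference set dropped")
  table
}

#' Write a community table as long-format CSV
#'
#' Columns `site, species, count` (plus `lat`, `lon` if coordinates exist).
#'
#' @param table a `community_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_communities <- function(table, path) {
  rows <- do.call(rbind, lapply(names(table$communities), function(s) {
    cm <- table$communities[[s]]
    if (length(cm) == 0L) return(NULL)
    data.frame(site = s, species = names(cm), count = as.numeric(cm),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(table$coords)) {
    rows$lat <- table$coords$lat[match(rows$site, table$coords$site)]
    rows$lon <- table$coords$lon[match(rows$site, table$coords$site)]
  }
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read a community table from long-format CSV
#'
#' @param path CSV with columns `site, species, count` (optional `lat`,
#'   `lon`); one row per species occurrence.
#' @param variant variant tag to record (default `"FULL"`).
#' @return a `community_table`.
#' @export
read_communities <- function(path, variant = "FULL") {
  tab <- collapse_years(read_survey_records(path))
  tab$variant <- variant
  tab
}
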