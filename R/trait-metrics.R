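## Mixed-type trait tables and Gower distances.  A trait table is a
## data.frame whose rownames are species labels; quantitative and ordinal
## columns are numeric (ordinal as level codes), nominal columns are
## character/factor.  Missing cells are NA.

#' Declare trait column types
#'
#' @param types named character vector mapping every trait column to one of
#'   `"quantitative"`, `"ordinal"`, `"nominal"`.
#' @param standardize named logical vector (or single logical) saying which
#'   quantitative columns to standardize by their mean; defaults to TRUE for
#'   all quantitative columns.
#' @return a `trait_type_spec` data.frame with columns `trait`, `type`,
#'   `standardize`.
#' @export
trait_type_spec <- function(types, standardize = TRUE) {
  if (is.null(names(types)) || any(!nzchar(names(types))))
    stop("'types' must be a named vector (names = trait columns)",
         call. = FALSE)
  types <- vapply(types, match.arg,
                  choices = c("quantitative", "ordinal", "nominal"),
                  FUN.VALUE = character(1))
  std <- rep_len(FALSE, length(types))
  names(std) <- names(types)
  quant <- types == "quantitative"
  if (is.logical(standardize) && length(standardize) == 1L) {
    std[quant] <- standardize
  } else {
    std[names(standardize)] <- as.logical(standardize)
    std[!quant] <- FALSE
  }
  structure(data.frame(trait = names(types), type = unname(types),
                       standardize = unname(std), stringsAsFactors = FALSE),
            class = c("trait_type_spec", "data.frame"))
}

.check_spec <- function(table, spec) {
  if (!inherits(spec, "trait_type_spec"))
    stop("'spec' must be a trait_type_spec", call. = FALSE)
  miss <- setdiff(names(table), spec$trait)
  extra <- setdiff(spec$trait, names(table))
  if (length(miss) || length(extra))
    stop("trait type spec must cover the table columns exactly (untyped: ",
         paste(miss, collapse = ", "), "; unknown: ",
         paste(extra, collapse = ", "), ")", call. = FALSE)
  invisible(spec)
}

#' Read a trait type spec from JSON or YAML
#'
#' The file maps each column name either to a type string or to an object
#' `{"type": ..., "standardize": ...}`.
#'
#' @param path path to a `.json`, `.yml` or `.yaml` file.
#' @return a [trait_type_spec()].
#' @export
read_trait_types <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is needed to read YAML specs", call. = FALSE)
    raw <- yaml::read_yaml(path)
  } else {
    raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  }
  types <- character(0); std <- logical(0)
  for (nm in names(raw)) {
    v <- raw[[nm]]
    if (is.character(v)) {
      types[nm] <- v
      std[nm] <- TRUE
    } else {
      types[nm] <- v$type
      std[nm] <- if (is.null(v$standardize)) TRUE else isTRUE(v$standardize)
    }
  }
  trait_type_spec(types, std)
}

#' Write a trait type spec as JSON
#'
#' @param spec a [trait_type_spec()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trait_types <- function(spec, path) {
  obj <- stats::setNames(lapply(seq_len(nrow(spec)), function(i)
    list(type = spec$type[i], standardize = spec$standardize[i])), spec$trait)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a species trait table from CSV
#'
#' First column (or a column named `species`) holds unique species labels;
#' missing values are empty cells or `NA`.  Columns are coerced according to
#' the type spec: quantitative and ordinal to numeric, nominal to character.
#'
#' @param path CSV path with a header row.
#' @param spec a [trait_type_spec()] covering the trait columns.
#' @return data.frame of traits with species labels as rownames.
#' @export
read_trait_table <- function(path, spec) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"), check.names = FALSE)
  key <- if ("species" %in% names(raw)) "species" else names(raw)[1L]
  if (anyDuplicated(raw[[key]]))
    stop("duplicate species labels in trait table", call. = FALSE)
  tab <- raw[setdiff(names(raw), key)]
  rownames(tab) <- raw[[key]]
  .check_spec(tab, spec)
  for (i in seq_len(nrow(spec))) {
    cn <- spec$trait[i]
    if (spec$type[i] %in% c("quantitative", "ordinal"))
      tab[[cn]] <- as.numeric(tab[[cn]])
    else
      tab[[cn]] <- as.character(tab[[cn]])
  }
  tab
}

#' Standardize quantitative trait columns by their mean
#'
#' Divides each flagged quantitative column element-wise by its mean over
#' non-missing entries, so traits on very different scales become
#' comparable while staying non-negative for typical positive traits.
#' An optional centering variant subtracts the mean instead.
#'
#' @param table trait data.frame (rownames = species).
#' @param spec a [trait_type_spec()]; only columns with `standardize = TRUE`
#'   are touched.
#' @param center if TRUE, subtract the column mean instead of dividing by it.
#' @return the table with standardized quantitative columns; missing cells
#'   stay missing.
#' @export
standardize_quantitative <- function(table, spec, center = FALSE) {
  .check_spec(table, spec)
  for (i in which(spec$standardize & spec$type == "quantitative")) {
    cn <- spec$trait[i]
    x <- table[[cn]]
    mu <- mean(x, na.rm = TRUE)
    if (!is.finite(mu) || (!center && mu == 0))
      stop("cannot standardize column '", cn, "': mean is ",
           if (is.finite(mu)) "zero" else "undefined", call. = FALSE)
    table[[cn]] <- if (center) x - mu else x / mu
  }
  table
}

#' Gower mixed-type trait distance matrix
#'
#' For each pair of species, averages per-column distances over the columns
#' where both species are non-missing: range-normalized absolute difference
#' for quantitative traits, the same on the rank scale for ordinal traits,
#' and simple mismatch (0/1) for nominal traits.  Columns with zero range
#' contribute distance 0 (with a warning).  Pairs sharing no comparable
#' column are left `NA` ("incomparable") for
#' [impute_incomparable_pairs()] to resolve.
#'
#' @param table trait data.frame (rownames = species, at least 2 rows).
#' @param spec a [trait_type_spec()].
#' @param scope scope tag (default `"GLOBAL"`).
#' @return a `trait_dist` object: list with the symmetric distance matrix
#'   `d` (entries in `[0, 1]`, zero diagonal), logical matrix `imputed`,
#'   and `scope`.
#' @export
gower_matrix <- function(table, spec, scope = "GLOBAL") {
  .check_spec(table, spec)
  n <- nrow(table)
  if (n < 2L)
    stop("need at least 2 species for a distance matrix", call. = FALSE)
  labels <- rownames(table)
  num <- matrix(0, n, n)
  den <- matrix(0L, n, n)
  for (i in seq_len(nrow(spec))) {
    x <- table[[spec$trait[i]]]
    ok <- !is.na(x)
    cmp <- outer(ok, ok, `&`)
    if (spec$type[i] == "nominal") {
      contrib <- matrix(0, n, n)
      xo <- x[ok]
      contrib[cmp] <- as.numeric(outer(xo, xo, `!=`))
    } else {
      v <- x
      if (spec$type[i] == "ordinal") {
        lev <- sort(unique(x[ok]))
        v[ok] <- match(x[ok], lev)
      }
      rng <- if (any(ok)) diff(range(v, na.rm = TRUE)) else 0
      if (!is.finite(rng) || rng == 0) {
        if (any(ok))
          warning("trait '", spec$trait[i],
                  "' has zero range; it contributes distance 0",
                  call. = FALSE)
        contrib <- matrix(0, n, n)
      } else {
        contrib <- abs(outer(v, v, `-`)) / rng
        contrib[!cmp] <- 0
      }
    }
    num <- num + contrib
    den <- den + cmp
  }
  d <- num / den          # NaN where no comparable columns
  d[!is.finite(d)] <- NA_real_
  diag(d) <- 0
  dimnames(d) <- list(labels, labels)
  structure(list(d = d,
                 imputed = matrix(FALSE, n, n, dimnames = list(labels, labels)),
                 scope = scope),
            class = "trait_dist")
}

#' @export
print.trait_dist <- function(x, ...) {
  cat(sprintf("Gower trait distance matrix: %d species, scope %s, %d imputed pair(s)\n",
              nrow(x$d), x$scope, sum(x$imputed[upper.tri(x$imputed)])))
  invisible(x)
}

#' Resolve incomparable species pairs by the median distance
#'
#' Pairs with no trait column comparable (both missing everywhere) are
#' awarded the median of all computable off-diagonal distances and marked in
#' the `imputed` mask.
#'
#' @param td a `trait_dist` from [gower_matrix()].
#' @return the `trait_dist` with no remaining `NA` entries.
#' @export
impute_incomparable_pairs <- function(td) {
  stopifnot(inherits(td, "trait_dist"))
  d <- td$d
  ut <- upper.tri(d)
  vals <- d[ut]
  if (all(is.na(vals)))
    stop("no computable species pairs: cannot impute", call. = FALSE)
  if (!anyNA(vals)) return(td)
  med <- stats::median(vals, na.rm = TRUE)
  miss <- is.na(d)
  d[miss] <- med
  td$d <- d
  td$imputed <- td$imputed | miss
  td
}

.complete_dist <- function(td) {
  stopifnot(inherits(td, "trait_dist"))
  if (anyNA(td$d))
    stop("distance matrix has unresolved incomparable pairs; ",
         "run impute_incomparable_pairs() first", call. = FALSE)
  td$d
}

#' Trait uniqueness (TU)
#'
#' Minimum Gower distance from each species to any other species in scope.
#'
#' @param td a complete `trait_dist` (see [impute_incomparable_pairs()]).
#' @return named numeric vector of TU scores.
#' @export
trait_uniqueness <- function(td) {
  d <- .complete_dist(td)
  if (nrow(d) < 2L)
    stop("need at least 2 species in scope", call. = FALSE)
  diag(d) <- Inf
  tu <- apply(d, 1L, min)
  names(tu) <- rownames(td$d)
  tu
}

#' Trait average pairwise distance (TAPD)
#'
#' Mean Gower distance from each species to all other species in scope
#' (self excluded; divisor `n - 1`).
#'
#' @inheritParams trait_uniqueness
#' @return named numeric vector of TAPD scores.
#' @export
trait_apd <- function(td) {
  d <- .complete_dist(td)
  n <- nrow(d)
  if (n < 2L)
    stop("need at least 2 species in scope", call. = FALSE)
  stats::setNames(rowSums(d) / (n - 1), rownames(d))
}

#' Restrict a trait distance matrix to a community
#'
#' Takes the principal submatrix over the given species and retags the
#' scope: local TU/TAPD are then recomputed on this submatrix while reusing
#' the globally computed pairwise distances.
#'
#' @param td a `trait_dist`.
#' @param species character vector of labels (subset of the matrix labels,
#'   at least 2).
#' @param scope new scope tag (default `"LOCAL"`).
#' @return a `trait_dist` over the subset.
#' @export
restrict_to_community <- function(td, species, scope = "LOCAL") {
  stopifnot(inherits(td, "trait_dist"))
  species <- unique(as.character(species))
  unknown <- setdiff(species, rownames(td$d))
  if (length(unknown))
    stop("unknown species label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (length(species) < 2L)
    stop("need at least 2 species in a community scope", call. = FALSE)
  structure(list(d = td$d[species, species, drop = FALSE],
                 imputed = td$imputed[species, species, drop = FALSE],
                 scope = scope),
            class = "trait_dist")
}

#' Mean pairwise trait distance of a species set
#'
#' The community-level summary used by the removal experiment: mean of all
#' off-diagonal pairwise Gower distances among the set.
#'
#' @param td a complete `trait_dist`.
#' @param species optional subset of labels (default: all in scope).
#' @return a single number, or `NA` if fewer than 2 species.
#' @export
mean_pairwise_trait_distance <- function(td, species = NULL) {
  d <- .complete_dist(td)
  if (!is.null(species)) {
    species <- intersect(unique(as.character(species)), rownames(d))
    d <- d[species, species, drop = FALSE]
  }
  k <- nrow(d)
  if (k < 2L) return(NA_real_)
  sum(d) / (k * (k - 1))
}

#' Full trait pipeline: standardize, Gower, impute
#'
#' Convenience wrapper chaining [standardize_quantitative()],
#' [gower_matrix()] and [impute_incomparable_pairs()].
#'
#' @inheritParams gower_matrix
#' @param standardize run mean-standardization first (default TRUE).
#' @return a complete `trait_dist`.
#' @export
trait_distance <- function(table, spec, scope = "GLOBAL", standardize = TRUE) {
  if (standardize) table <- standardize_quantitative(table, spec)
  impute_incomparable_pairs(gower_matrix(table, spec, scope = scope))
}

#' Trait scores (TU and TAPD) as a table
#'
#' @param td a complete `trait_dist`.
#' @return data.frame with columns `species`, `TU`, `TAPD`; `"scope"`
#'   attribute taken from the matrix.
#' @export
trait_scores <- function(td) {
  tu <- trait_uniqueness(td)
  tapd <- trait_apd(td)
  out <- data.frame(species = rownames(td$d), TU = unname(tu),
                    TAPD = unname(tapd), stringsAsFactors = FALSE)
  attr(out, "scope") <- td$scope
  out
}

#' Write a trait distance matrix as square CSV
#'
#' @param td a `trait_dist`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trait_dist <- function(td, path) {
  utils::write.csv(as.data.frame(td$d), path, row.names = TRUE)
  invisible(path)
}
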