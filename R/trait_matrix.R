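#' Binary trait matrix with trait-group labels
#'
#' A `trait_matrix` holds a genomes x traits binary (0/1) matrix together with
#' a group label per trait. Groups partition traits into the two families
#' whose association is under study plus a background pool:
#' `"system"` (e.g. DNA double-strand-break repair components), `"cas"`
#' (e.g. CRISPR-Cas subtypes) and `"control"` (background genes used as a
#' frequency-matched null for the phi screen).
#'
#' @param values integer/numeric matrix of 0/1 with unique rownames (genome
#'   ids) and unique colnames (trait ids).
#' @param groups character vector, one of `"system"`, `"cas"`, `"control"`
#'   per column of `values`; may be named by trait id.
#' @return an object of class `trait_matrix`: a list with elements `values`
#'   (integer matrix) and `groups` (named character vector).
#' @examples
#' m <- matrix(c(1, 0, 1, 0, 1, 1), nrow = 3,
#'             dimnames = list(c("g1", "g2", "g3"), c("sysA", "casX")))
#' tm <- trait_matrix(m, c("system", "cas"))
#' trait_freq(tm)
#' @export
trait_matrix <- function(values, groups) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have rownames (genome ids) and colnames (trait ids)")
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicated genome id: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicated trait id: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  }
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing cell at genome '%s', trait '%s'",
                 rownames(values)[bad[1L]], colnames(values)[bad[2L]]))
  }
  if (!all(values %in% c(0, 1))) {
    bad <- which(!(values %in% c(0, 1)))[1L]
    idx <- arrayInd(bad, dim(values))
    stop(sprintf("non-binary cell value '%s' at genome '%s', trait '%s'",
                 values[bad], rownames(values)[idx[1L]],
                 colnames(values)[idx[2L]]))
  }
  groups <- as.character(groups)
  if (length(groups) != ncol(values)) {
    stop("`groups` must have one entry per trait column")
  }
  ok <- groups %in% c("system", "cas", "control")
  if (!all(ok)) {
    stop("unknown trait group label: ", paste(unique(groups[!ok]), collapse = ", "),
         " (expected system/cas/control)")
  }
  storage.mode(values) <- "integer"
  structure(list(values = values, groups = setNames(groups, colnames(values))),
            class = "trait_matrix")
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat(sprintf("trait_matrix: %d genomes x %d traits (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%d %s", table(factor(x$groups,
                levels = c("system", "cas", "control"))),
                c("system", "cas", "control")), collapse = ", ")))
  invisible(x)
}

#' @export
dim.trait_matrix <- function(x) dim(x$values)

#' Presence frequency of each trait
#'
#' @param tm a [trait_matrix].
#' @return named numeric vector of presence frequencies in `[0, 1]`.
#' @export
trait_freq <- function(tm) {
  stopifnot(inherits(tm, "trait_matrix"))
  colMeans(tm$values)
}

#' Trait ids belonging to a group
#'
#' @param tm a [trait_matrix].
#' @param group one of `"system"`, `"cas"`, `"control"`.
#' @return character vector of trait ids.
#' @export
traits_in_group <- function(tm, group) {
  stopifnot(inherits(tm, "trait_matrix"))
  group <- match.arg(group, c("system", "cas", "control"))
  names(tm$groups)[tm$groups == group]
}

#' Restrict a trait matrix to a subset of genomes and/or traits
#'
#' @param tm a [trait_matrix].
#' @param genomes,traits character vectors of ids to keep (default: all).
#' @return a [trait_matrix].
#' @export
subset_traits <- function(tm, genomes = NULL, traits = NULL) {
  stopifnot(inherits(tm, "trait_matrix"))
  genomes <- genomes %||% rownames(tm$values)
  traits <- traits %||% colnames(tm$values)
  missing_g <- setdiff(genomes, rownames(tm$values))
  if (length(missing_g)) stop("unknown genome id: ", paste(missing_g, collapse = ", "))
  missing_t <- setdiff(traits, colnames(tm$values))
  if (length(missing_t)) stop("unknown trait id: ", paste(missing_t, collapse = ", "))
  trait_matrix(tm$values[genomes, traits, drop = FALSE], tm$groups[traits])
}

#' Column-bind trait matrices over the same genomes
#'
#' @param ... [trait_matrix] objects with identical genome id sets.
#' @return a [trait_matrix] with the union of trait columns.
#' @export
cbind_traits <- function(...) {
  tms <- list(...)
  stopifnot(length(tms) >= 1L, all(vapply(tms, inherits, TRUE, "trait_matrix")))
  ids <- rownames(tms[[1L]]$values)
  vals <- lapply(tms, function(tm) {
    if (!setequal(rownames(tm$values), ids)) {
      stop("trait matrices cover different genome sets")
    }
    tm$values[ids, , drop = FALSE]
  })
  trait_matrix(do.call(cbind, vals),
               unlist(lapply(tms, function(tm) unname(tm$groups))))
}

#' Read a trait table from delimited text
#'
#' The expected layout is a header row of trait ids (first field names the
#' genome-id column), a second row starting with `#group:` giving the group
#' label of each trait, then one row per genome with 0/1 values. Keeping the
#' group annotation inside the file means one file fully specifies a matrix.
#'
#' @param path path to the table.
#' @param sep field delimiter (default tab).
#' @return a validated [trait_matrix].
#' @export
read_trait_table <- function(path, sep = "\t") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 3L) stop("trait table needs a header, a #group: row and data")
  split1 <- strsplit(lines, sep, fixed = TRUE)
  header <- split1[[1L]]
  trait_ids <- header[-1L]
  grow <- split1[[2L]]
  if (grow[1L] != "#group:") {
    stop("second row must start with '#group:' and label each trait")
  }
  groups <- grow[-1L]
  if (length(groups) != length(trait_ids)) {
    stop("#group: row has ", length(groups), " labels for ",
         length(trait_ids), " traits")
  }
  body <- split1[-(1:2)]
  n_fields <- lengths(body)
  if (any(n_fields != length(trait_ids) + 1L)) {
    stop("row ", which(n_fields != length(trait_ids) + 1L)[1L] + 2L,
         " has the wrong number of fields")
  }
  genome_ids <- vapply(body, `[[`, "", 1L)
  raw <- t(vapply(body, function(f) f[-1L], character(length(trait_ids))))
  num <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw)))
  bad <- is.na(num) | !(num %in% c(0, 1))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-binary cell '%s' at genome '%s', trait '%s'",
                 raw[idx[1L], idx[2L]], genome_ids[idx[1L]], trait_ids[idx[2L]]))
  }
  dimnames(num) <- list(genome_ids, trait_ids)
  trait_matrix(num, groups)
}

#' Write a trait table
#'
#' Inverse of [read_trait_table()]; writes the two-header-row layout.
#'
#' @param tm a [trait_matrix].
#' @param path output path.
#' @param sep field delimiter (default tab).
#' @export
write_trait_table <- function(tm, path, sep = "\t") {
  stopifnot(inherits(tm, "trait_matrix"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c("genome_id", colnames(tm$values)), collapse = sep), con)
  writeLines(paste(c("#group:", unname(tm$groups)), collapse = sep), con)
  body <- apply(tm$values, 1L, paste, collapse = sep)
  writeLines(paste(rownames(tm$values), body, sep = sep), con)
  invisible(path)
}
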