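#' Read a sire-maternal-grandsire pedigree file
#'
#' Parses a three-column delimited text file (individual, sire, maternal
#' grandsire) into a validated, topologically ordered pedigree. Unknown
#' parents are coded `"0"`, `"NA"` or empty. Individual ids are opaque
#' strings; rows may appear in any order (ancestors are sorted before
#' descendants).
#'
#' @param path Path to a delimited text file. Delimiter is auto-detected by
#'   [readr::read_delim()] from commas, tabs or whitespace.
#' @param col_names Does the file have a header row? Default `TRUE`.
#' @return A tibble of class `sire_mgs_pedigree` with columns `id`, `sire`,
#'   `mgs` (NA for unknown), ordered so parents precede offspring.
#' @export
read_pedigree <- function(path, col_names = TRUE) {
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first)) "," else ""
  raw <- utils::read.table(path, header = col_names, sep = sep,
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(raw) != 3) {
    stop("pedigree file must have exactly 3 columns (id, sire, mgs)",
         call. = FALSE)
  }
  names(raw) <- c("id", "sire", "mgs")
  as_pedigree(raw)
}

#' Construct a validated pedigree from a data frame
#'
#' @param x Data frame with columns `id`, `sire`, `mgs`. `"0"`, `""` and NA
#'   mark unknown parents.
#' @return A tibble of class `sire_mgs_pedigree`, topologically ordered.
#' @export
as_pedigree <- function(x) {
  stopifnot(all(c("id", "sire", "mgs") %in% names(x)))
  ped <- tibble::tibble(
    id   = as.character(x$id),
    sire = clean_parent(x$sire),
    mgs  = clean_parent(x$mgs)
  )
  if (anyDuplicated(ped$id)) {
    stop("duplicate individual(s) in pedigree: ",
         paste(unique(ped$id[duplicated(ped$id)]), collapse = ", "),
         call. = FALSE)
  }
  # parents referenced but never listed become implicit founders
  ghosts <- setdiff(stats::na.omit(c(ped$sire, ped$mgs)), ped$id)
  if (length(ghosts)) {
    ped <- dplyr::bind_rows(
      tibble::tibble(id = ghosts, sire = NA_character_, mgs = NA_character_),
      ped
    )
  }
  idx <- match(ped$id, ped$id)
  sidx <- match(ped$sire, ped$id)
  midx <- match(ped$mgs, ped$id)
  ord <- pedigree_topo_order(nrow(ped), sidx, midx, ped$id)
  ped <- ped[ord, ]
  class(ped) <- c("sire_mgs_pedigree", class(ped))
  ped
}

clean_parent <- function(p) {
  p <- as.character(p)
  p[is.na(p) | p %in% c("0", "", "NA", ".")] <- NA_character_
  p
}

pedigree_topo_order <- function(n, sidx, midx, ids) {
  state <- integer(n)
  order <- integer(0)
  visit <- function(v) {
    if (state[v] == 1L) {
      stop("individual ", ids[v], " is its own ancestor (pedigree loop)",
           call. = FALSE)
    }
    if (state[v] == 2L) return(invisible())
    state[v] <<- 1L
    for (w in c(sidx[v], midx[v])) {
      if (!is.na(w)) visit(w)
    }
    state[v] <<- 2L
    order <<- c(order, v)
    invisible()
  }
  for (v in seq_len(n)) visit(v)
  order
}

#' Numerator relationship matrix from a sire-MGS pedigree
#'
#' Builds the numerator relationship matrix A among bulls recorded with
#' their sire and maternal grandsire (MGS), by the tabular method with the
#' sire-MGS recursion: the relationship of a new individual to any earlier
#' one is half its relationship through the sire plus a quarter through the
#' MGS, and its own diagonal is `1 + 0.25 * a(sire, mgs)`. Unknown parents
#' contribute as unrelated founders. A prior on sire genetic effects
#' `s ~ N(0, G (x) A)` uses this matrix.
#'
#' @param ped A `sire_mgs_pedigree` (see [read_pedigree()]).
#' @return List of class `relationship_matrix` with elements `A` (dense
#'   symmetric matrix with id dimnames), `A_inv` (its inverse) and `ids`.
#' @export
relationship_matrix <- function(ped) {
  stopifnot(inherits(ped, "sire_mgs_pedigree"))
  n <- nrow(ped)
  ids <- ped$id
  sidx <- match(ped$sire, ids)
  midx <- match(ped$mgs, ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (k in seq_len(n)) {
    s <- sidx[k]
    m <- midx[k]
    if (k > 1) {
      prev <- seq_len(k - 1L)
      rel <- numeric(k - 1L)
      if (!is.na(s)) rel <- rel + 0.5 * A[prev, s]
      if (!is.na(m)) rel <- rel + 0.25 * A[prev, m]
      A[prev, k] <- rel
      A[k, prev] <- rel
    }
    A[k, k] <- 1 + if (!is.na(s) && !is.na(m)) 0.25 * A[s, m] else 0
  }
  ev_min <- min(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min <= 1e-10) {
    stop("relationship matrix is not positive definite ",
         "(pedigree inconsistency; smallest eigenvalue ", signif(ev_min, 3),
         ")", call. = FALSE)
  }
  A_inv <- chol2inv(chol(A))
  dimnames(A_inv) <- dimnames(A)
  structure(list(A = A, A_inv = A_inv, ids = ids),
            class = "relationship_matrix")
}

#' @export
print.relationship_matrix <- function(x, ...) {
  cat("<relationship_matrix> ", length(x$ids), " individuals, mean diagonal ",
      round(mean(diag(x$A)), 4), "\n", sep = "")
  invisible(x)
}

#' Write a pedigree to delimited text
#'
#' @param ped A `sire_mgs_pedigree`.
#' @param path Output file path. Unknown parents are written as `0`.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  out <- tibble::as_tibble(ped)
  out$sire[is.na(out$sire)] <- "0"
  out$mgs[is.na(out$mgs)] <- "0"
  readr::write_tsv(out, path)
  invisible(path)
}
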