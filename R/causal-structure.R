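#' Canonical milk-trait panel
#'
#' The four jointly analysed test-day traits in their canonical order:
#' somatic cell score (SCS, log units), casein percentage (CAS, %), rennet
#' coagulation time (RCT, min) and curd firmness 30 min after rennet
#' addition (a30, mm). All matrix layouts in the package follow this order.
#'
#' @return Character vector of length 4.
#' @export
#' @examples
#' milk_traits()
milk_traits <- function() c("SCS", "CAS", "RCT", "a30")

#' Declare a recursive causal structure among traits
#'
#' Builds a directed acyclic graph of contemporaneous (within-record) causal
#' effects among phenotypes. An edge `x -> y` means phenotype `x` has a
#' direct causal effect on phenotype `y`, with structural coefficient
#' `lambda[y, x]` in units of y per unit of x. Acyclicity is certified at
#' construction by depth-first search and a topological order is recorded.
#'
#' @param edges A data frame (or tibble) with columns `from` and `to`
#'   containing trait names, or a list of length-2 character vectors
#'   `c(from, to)`. An empty set declares the baseline multiple-trait model
#'   (no causal paths).
#' @param traits Ordered character vector of trait labels; defaults to
#'   [milk_traits()]. The declared order fixes all matrix layouts.
#' @return An object of class `causal_structure`: a list with `traits`,
#'   `edges` (tibble with `from`, `to`, `from_idx`, `to_idx`), and
#'   `topo_order` (trait indices, parents before children).
#' @export
#' @examples
#' causal_structure(list(c("RCT", "a30"))) # curd firmness depends on RCT
#' model_preset("M1")
causal_structure <- function(edges = NULL, traits = milk_traits()) {
  stopifnot(is.character(traits), length(traits) >= 1)
  if (anyDuplicated(traits)) {
    stop("trait labels must be unique", call. = FALSE)
  }
  edges <- normalise_edges(edges)
  bad <- setdiff(c(edges$from, edges$to), traits)
  if (length(bad)) {
    stop("unknown trait(s) in edge list: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(edges$from == edges$to)) {
    stop("self-edges are not allowed", call. = FALSE)
  }
  edges <- dplyr::mutate(
    edges,
    from_idx = match(.data$from, traits),
    to_idx   = match(.data$to, traits)
  )
  if (anyDuplicated(edges[c("from", "to")])) {
    stop("duplicate edges in structure", call. = FALSE)
  }
  topo <- topological_order(length(traits), edges$from_idx, edges$to_idx,
                            traits)
  structure(
    list(traits = traits, edges = edges, topo_order = topo),
    class = "causal_structure"
  )
}

normalise_edges <- function(edges) {
  if (is.null(edges) || (is.list(edges) && length(edges) == 0)) {
    return(tibble::tibble(from = character(), to = character()))
  }
  if (is.data.frame(edges)) {
    stopifnot(all(c("from", "to") %in% names(edges)))
    return(tibble::as_tibble(edges[c("from", "to")]))
  }
  if (is.list(edges)) {
    stopifnot(all(vapply(edges, length, 1L) == 2L))
    return(tibble::tibble(
      from = vapply(edges, function(e) as.character(e[[1]]), ""),
      to   = vapply(edges, function(e) as.character(e[[2]]), "")
    ))
  }
  stop("`edges` must be NULL, a data frame with from/to, or a list of pairs",
       call. = FALSE)
}

# DFS topological sort; reports the offending cycle by trait name on failure.
topological_order <- function(n, from_idx, to_idx, traits) {
  adj <- vector("list", n) # children of each node
  for (k in seq_along(from_idx)) {
    adj[[from_idx[k]]] <- c(adj[[from_idx[k]]], to_idx[k])
  }
  state <- integer(n) # 0 unvisited, 1 on stack, 2 done
  order <- integer(0)
  path <- integer(0)
  visit <- function(v) {
    if (state[v] == 1L) {
      cyc <- c(path[which(path == v)[1]:length(path)], v)
      stop("causal structure contains a cycle: ",
           paste(traits[cyc], collapse = " -> "),
           " (structural coefficients are not identifiable)", call. = FALSE)
    }
    if (state[v] == 2L) return(invisible())
    state[v] <<- 1L
    path <<- c(path, v)
    for (w in adj[[v]]) visit(w)
    path <<- path[-length(path)]
    state[v] <<- 2L
    order <<- c(v, order)
    invisible()
  }
  for (v in seq_len(n)) visit(v)
  order
}

#' Named model presets for the fitted causal structures
#'
#' Returns the causal structures fitted in the source study design:
#' `"M0"` the baseline multiple-trait model (no causal paths); `"M1"` effects
#' of SCS and CAS on both RCT and a30; `"M2"` the single effect of RCT on
#' a30; `"M3"` effects of SCS, CAS and RCT on a30; `"M1-SCS"` and `"M1-CAS"`
#' the two auxiliary reductions of M1 with only the SCS (resp. CAS) effects.
#'
#' @param name One of `"M0"`, `"M1"`, `"M2"`, `"M3"`, `"M1-SCS"`, `"M1-CAS"`.
#' @return A [causal_structure()].
#' @export
model_preset <- function(name) {
  presets <- list(
    "M0" = list(),
    "M1" = list(c("SCS", "RCT"), c("CAS", "RCT"),
                c("SCS", "a30"), c("CAS", "a30")),
    "M2" = list(c("RCT", "a30")),
    "M3" = list(c("SCS", "a30"), c("CAS", "a30"), c("RCT", "a30")),
    "M1-SCS" = list(c("SCS", "RCT"), c("SCS", "a30")),
    "M1-CAS" = list(c("CAS", "RCT"), c("CAS", "a30"))
  )
  if (!name %in% names(presets)) {
    stop("unknown model preset: ", name, " (expected one of ",
         paste(names(presets), collapse = ", "), ")", call. = FALSE)
  }
  causal_structure(presets[[name]])
}

#' Build the structural coefficient matrix Lambda
#'
#' Places edge coefficients into the square matrix Lambda, with the
#' coefficient for edge `x -> y` at row y, column x and zeros elsewhere.
#' The model is `y = Lambda y + Xb + ... + e`, so `(I - Lambda)` maps
#' phenotypes to their structural (causality-free) scale.
#'
#' @param structure A [causal_structure()].
#' @param values Named numeric vector or list keyed `"from->to"` (e.g.
#'   `c("RCT->a30" = -1.901)`), or a numeric vector in the order of
#'   `structure$edges`. Must supply exactly one value per edge.
#' @return A square numeric matrix with trait dimnames.
#' @export
#' @examples
#' lambda_matrix(model_preset("M2"), c("RCT->a30" = -1.901))
lambda_matrix <- function(structure, values = numeric()) {
  stopifnot(inherits(structure, "causal_structure"))
  tr <- structure$traits
  n <- length(tr)
  L <- matrix(0, n, n, dimnames = list(tr, tr))
  e <- structure$edges
  if (nrow(e) == 0) {
    if (length(values)) stop("structure has no edges but values were supplied",
                             call. = FALSE)
    return(L)
  }
  keys <- edge_keys(structure)
  values <- unlist(values)
  if (is.null(names(values)) || all(names(values) == "")) {
    if (length(values) != nrow(e)) {
      stop("expected ", nrow(e), " coefficients, got ", length(values),
           call. = FALSE)
    }
    names(values) <- keys
  }
  missing <- setdiff(keys, names(values))
  extra <- setdiff(names(values), keys)
  if (length(missing)) stop("missing coefficient(s): ",
                            paste(missing, collapse = ", "), call. = FALSE)
  if (length(extra)) stop("coefficient(s) for edges not in structure: ",
                          paste(extra, collapse = ", "), call. = FALSE)
  L[cbind(e$to_idx, e$from_idx)] <- as.numeric(values[keys])
  L
}

edge_keys <- function(structure) {
  if (nrow(structure$edges) == 0) return(character(0))
  paste0(structure$edges$from, "->", structure$edges$to)
}

#' @export
print.causal_structure <- function(x, ...) {
  cat("<causal_structure> traits:", paste(x$traits, collapse = ", "), "\n")
  if (nrow(x$edges) == 0) {
    cat("  no causal paths (multiple-trait model)\n")
  } else {
    cat("  edges:", paste(edge_keys(x), collapse = ", "), "\n")
  }
  invisible(x)
}
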