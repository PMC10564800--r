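# Readers and writers.
#
# Edge-list format: UTF-8 text, one "parent<TAB>child" line per arc,
# '#'-comments and blank lines ignored; leaf labels default to vertex ids
# and can be overridden by "label<TAB>vertex<TAB>name" lines.
#
# Extended Newick: the common dialect with #H<int> hybrid tags; the first
# occurrence of a tag may carry the subtree, all later occurrences are
# leaf-like references.  Internal vertex labels are optional and ignored.

#' Read and write networks as tab-separated edge lists
#'
#' @param path file path
#' @param N a `phynet`
#' @return `read_edgelist` a `phynet`; `write_edgelist` invisibly `path`
#' @export
read_edgelist <- function(path) {
  lines <- readLines(path, warn = FALSE)
  arcs <- list()
  labels <- character(0)
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[[i]])
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) == 3L && parts[[1L]] == "label") {
      labels[[parts[[2L]]]] <- parts[[3L]]
    } else if (length(parts) == 2L) {
      arcs[[length(arcs) + 1L]] <- parts
    } else {
      phyclus_stop("ParseError", sprintf("line %d: expected 2 fields, got %d",
                                         i, length(parts)))
    }
  }
  if (length(arcs) == 0L)
    phyclus_stop("ParseError", "no arcs in edge-list file")
  e <- do.call(rbind, arcs)
  leaves <- setdiff(unique(c(e)), e[, 1L])
  full <- stats::setNames(leaves, leaves)
  full[names(labels)[names(labels) %in% leaves]] <-
    labels[names(labels) %in% leaves]
  build_network(e, leaf_labels = full)
}

#' @rdname read_edgelist
#' @export
write_edgelist <- function(N, path) {
  lines <- apply(N$edges, 1L, paste, collapse = "\t")
  relab <- N$labels[names(N$labels) != unname(N$labels)]
  if (length(relab) > 0L)
    lines <- c(lines, paste("label", names(relab), unname(relab), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

# ---- extended Newick -------------------------------------------------------

#' Read and write networks in extended Newick
#'
#' Hybrid vertices are encoded with `#H<k>` tags: exactly one occurrence of
#' a tag may carry children, every other occurrence is a leaf-like reference
#' that is merged into the same vertex on reading.  A tag used only once is
#' an error (`UnmatchedHybridTag`).  Writing picks, for each hybrid, the
#' lexicographically smallest parent as the one under which the subtree is
#' printed.  Internal labels are not written; leaf ids in the parsed network
#' equal the leaf labels.
#'
#' @param text a single extended-Newick string (terminated by `;`)
#' @param N a `phynet`
#' @return `read_enewick` a `phynet`; `write_enewick` a character scalar
#' @export
read_enewick <- function(text) {
  s <- gsub("[[:space:]]", "", text)
  if (!endsWith(s, ";")) phyclus_stop("ParseError", "missing terminal ';'")
  s <- substr(s, 1L, nchar(s) - 1L)
  pos <- 1L
  n_chr <- nchar(s)
  peek <- function() if (pos <= n_chr) substr(s, pos, pos) else ""
  node_ct <- 0L
  arcs <- list()
  # per node: id, name, tag, has_children
  nodes <- list()
  new_node <- function(name, tag, has_children) {
    node_ct <<- node_ct + 1L
    id <- paste0(".n", node_ct)
    nodes[[id]] <<- list(name = name, tag = tag, has_children = has_children)
    id
  }
  read_name <- function() {
    start <- pos
    while (pos <= n_chr && !(peek() %in% c("(", ")", ",", "#"))) pos <<- pos + 1L
    substr(s, start, pos - 1L)
  }
  read_tag <- function() {
    if (peek() != "#") return(NA_character_)
    pos <<- pos + 1L
    tag <- read_name()
    if (!grepl("^H[0-9]+$", tag))
      phyclus_stop("ParseError", paste("malformed hybrid tag #", tag))
    tag
  }
  parse_subtree <- function() {
    if (peek() == "(") {
      pos <<- pos + 1L
      kids <- list()
      repeat {
        kids[[length(kids) + 1L]] <- parse_subtree()
        if (peek() == ",") { pos <<- pos + 1L; next }
        if (peek() == ")") { pos <<- pos + 1L; break }
        phyclus_stop("ParseError", sprintf("unexpected character at %d", pos))
      }
      name <- read_name()
      tag <- read_tag()
      id <- new_node(name, tag, TRUE)
      for (k in kids) arcs[[length(arcs) + 1L]] <<- c(id, k)
      id
    } else {
      name <- read_name()
      tag <- read_tag()
      if (!nzchar(name) && is.na(tag))
        phyclus_stop("ParseError", sprintf("empty node at position %d", pos))
      new_node(name, tag, FALSE)
    }
  }
  root <- parse_subtree()
  if (pos <= n_chr) phyclus_stop("ParseError", "trailing characters")
  # merge hybrid tags
  tags <- vapply(nodes, function(n) ifelse(is.na(n$tag), "", n$tag), character(1))
  canon <- stats::setNames(names(nodes), names(nodes))
  for (tg in setdiff(unique(tags), "")) {
    occ <- names(nodes)[tags == tg]
    if (length(occ) < 2L)
      phyclus_stop("UnmatchedHybridTag", paste("tag used only once: #", tg))
    withk <- occ[vapply(occ, function(i) nodes[[i]]$has_children, logical(1))]
    if (length(withk) > 1L)
      phyclus_stop("ParseError", paste("tag with several subtrees: #", tg))
    target <- if (length(withk) == 1L) withk else occ[[1L]]
    nm <- unique(Filter(nzchar, vapply(occ, function(i) nodes[[i]]$name, character(1))))
    if (length(nm) > 1L)
      phyclus_stop("ParseError", paste("conflicting labels on tag #", tg))
    if (length(nm) == 1L) nodes[[target]]$name <- nm
    canon[occ] <- target
  }
  e <- do.call(rbind, lapply(arcs, function(a) c(canon[[a[1L]]], canon[[a[2L]]])))
  if (is.null(e)) {
    # a single vertex, e.g. "x;"
    nm <- nodes[[root]]$name
    return(build_network(NULL, isolated_root = nm))
  }
  e <- e[!duplicated(paste(e[, 1L], e[, 2L], sep = "\r")), , drop = FALSE]
  leaves <- setdiff(unique(c(e)), e[, 1L])
  labs <- vapply(leaves, function(i) nodes[[i]]$name, character(1))
  if (any(!nzchar(labs)))
    phyclus_stop("ParseError", "unlabeled leaf in input")
  if (anyDuplicated(labs))
    phyclus_stop("ParseError", "duplicated leaf label")
  # rename leaves to their labels, inner nodes to v1, v2, ...
  ren <- stats::setNames(labs, leaves)
  inner <- setdiff(unique(c(e)), leaves)
  ren[inner] <- paste0("v", seq_along(inner))
  e[, 1L] <- ren[e[, 1L]]
  e[, 2L] <- ren[e[, 2L]]
  build_network(e)
}

#' @rdname read_enewick
#' @export
write_enewick <- function(N) {
  if (nrow(N$edges) == 0L) return(paste0(unname(N$labels), ";"))
  ind <- nw_indeg(N)
  hyb <- sort(names(which(ind > 1L)))
  tag <- stats::setNames(paste0("#H", seq_along(hyb)), hyb)
  primary <- stats::setNames(vapply(hyb, function(h) min(nw_parents(N, h)),
                                    character(1)), hyb)
  render <- function(v, via) {
    is_hyb <- v %in% hyb
    if (is_hyb && !identical(primary[[v]], via)) return(tag[[v]])
    kids <- sort(nw_children(N, v))
    lab <- if (v %in% names(N$labels)) N$labels[[v]] else ""
    suffix <- paste0(lab, if (is_hyb) tag[[v]] else "")
    if (length(kids) == 0L) return(suffix)
    paste0("(", paste(vapply(kids, function(k) render(k, v), character(1)),
                      collapse = ","), ")", suffix)
  }
  paste0(render(N$root, NA_character_), ";")
}

# ---- clustering systems ----------------------------------------------------

#' Read and write clustering systems
#'
#' JSON form: `{"X": [labels], "clusters": [[labels], ...]}`.  Plain-text
#' form: one cluster per line, members comma-separated.  On reading, the
#' ground set and missing singletons are auto-added unless `strict = TRUE`,
#' in which case their absence is an error; whether completion happened is
#' recorded in attribute `completed` of the result.
#'
#' @param path file path
#' @param CS a `clustsys`
#' @param strict reject incomplete systems instead of completing them
#' @return `read_clustsys_*` a `clustsys`; writers invisibly `path`
#' @export
read_clustsys_json <- function(path, strict = FALSE) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(obj$clusters))
    phyclus_stop("ParseError", "JSON object must contain 'clusters'")
  X <- if (!is.null(obj$X)) unlist(obj$X) else NULL
  clustsys(lapply(obj$clusters, unlist), X = X, auto_complete = !strict)
}

#' @rdname read_clustsys_json
#' @export
write_clustsys_json <- function(CS, path) {
  jsonlite::write_json(list(X = CS$X, clusters = CS$clusters), path)
  invisible(path)
}

#' @rdname read_clustsys_json
#' @export
read_clustsys_text <- function(path, strict = FALSE) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) phyclus_stop("ParseError", "empty clustering system")
  clusters <- lapply(strsplit(lines, ","), trimws)
  clustsys(clusters, auto_complete = !strict)
}

#' @rdname read_clustsys_json
#' @export
write_clustsys_text <- function(CS, path) {
  writeLines(vapply(CS$clusters, paste, character(1), collapse = ","), path)
  invisible(path)
}
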