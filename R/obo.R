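#' Construct an ontology object
#'
#' An ontology is a directed acyclic graph of terms: each term has an id, a
#' name, a namespace and a set of parent ids (more general terms). Child
#' edges are the inverse of parent edges; `children` is derived and kept in
#' the object so traversal never re-inverts the mapping.
#'
#' @param terms A data frame with columns `id`, `name`, `namespace`.
#' @param parents Named list: term id -> character vector of parent term ids.
#' @return An object of class `inflamark_ontology`.
#' @export
ontology <- function(terms, parents) {
  terms <- tibble::as_tibble(terms)
  stopifnot(all(c("id", "name", "namespace") %in% names(terms)))
  if (anyDuplicated(terms$id)) {
    stop("duplicate term ids in ontology", call. = FALSE)
  }
  parents <- parents[terms$id]
  names(parents) <- terms$id
  parents <- lapply(parents, function(p) {
    if (is.null(p)) character() else unique(p)
  })
  dangling <- setdiff(unique(unlist(parents)), terms$id)
  if (length(dangling)) {
    stop("parent ids not present as terms: ",
         paste(dangling, collapse = ", "), call. = FALSE)
  }
  children <- invert_edges(parents, terms$id)
  obj <- structure(
    list(terms = terms, parents = parents, children = children),
    class = "inflamark_ontology"
  )
  assert_acyclic(obj)
  obj
}

invert_edges <- function(parents, ids) {
  children <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) {
    for (p in parents[[id]]) {
      children[[p]] <- c(children[[p]], id)
    }
  }
  lapply(children, function(x) if (is.null(x)) character() else unique(x))
}

# Kahn topological sort on parent edges; errors on cycles.
assert_acyclic <- function(onto) {
  ids <- onto$terms$id
  indeg <- vapply(onto$parents, length, integer(1))
  queue <- ids[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    cur <- queue[1L]; queue <- queue[-1L]; seen <- seen + 1L
    for (ch in onto$children[[cur]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen != length(ids)) {
    stop("ontology parent graph contains a cycle", call. = FALSE)
  }
  invisible(onto)
}

#' @export
print.inflamark_ontology <- function(x, ...) {
  n_edges <- sum(vapply(x$parents, length, integer(1)))
  cat(sprintf("inflamark ontology: %d terms, %d parent edges\n",
              nrow(x$terms), n_edges))
  invisible(x)
}

#' Number of terms in an ontology
#' @param onto An `inflamark_ontology`.
#' @return Integer term count.
#' @export
n_terms <- function(onto) nrow(onto$terms)

#' Read an OBO 1.2 ontology file
#'
#' Parses `[Term]` stanzas with `id`, `name`, `namespace`, `is_a`,
#' `relationship` and `is_obsolete` tags. Obsolete terms are dropped. Parent
#' edges come from `is_a` and `relationship: part_of`; other relationship
#' types are ignored with a warning, since descendant semantics for tissue
#' and immune processes conventionally use those two edge types only.
#' Trailing `! comment` text after a tag value is stripped.
#'
#' @param path Path to an OBO file.
#' @return An [ontology()] object.
#' @export
read_obo <- function(path) {
  if (!file.exists(path)) stop("OBO file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  in_term <- FALSE
  cur <- NULL
  stanzas <- list()
  flush <- function(cur) if (!is.null(cur) && !is.null(cur$id)) c(stanzas, list(cur)) else stanzas
  ignored_rel <- character()
  for (i in seq_along(lines)) {
    line <- sub("\\s+$", "", lines[[i]])
    if (line == "") next
    if (grepl("^\\[", line)) {
      stanzas <- flush(cur)
      cur <- NULL
      in_term <- identical(line, "[Term]")
      if (in_term) cur <- list(parents = character(), obsolete = FALSE)
      next
    }
    if (!in_term) next
    m <- regmatches(line, regexec("^([A-Za-z_]+):\\s*(.*)$", line))[[1]]
    if (length(m) != 3L) {
      stop(sprintf("malformed OBO stanza line %d: '%s'", i, line),
           call. = FALSE)
    }
    tag <- m[2]
    val <- sub("\\s*!.*$", "", m[3])
    if (tag == "id") {
      if (is.null(cur$id)) cur$id <- val
    } else if (tag == "name") {
      cur$name <- val
    } else if (tag == "namespace") {
      cur$namespace <- val
    } else if (tag == "is_a") {
      cur$parents <- c(cur$parents, val)
    } else if (tag == "is_obsolete") {
      cur$obsolete <- identical(tolower(val), "true")
    } else if (tag == "relationship") {
      parts <- strsplit(trimws(val), "\\s+")[[1]]
      if (length(parts) < 2L) {
        stop(sprintf("malformed relationship at line %d: '%s'", i, line),
             call. = FALSE)
      }
      if (parts[1] == "part_of") {
        cur$parents <- c(cur$parents, parts[2])
      } else {
        ignored_rel <- c(ignored_rel, parts[1])
      }
    }
    # other tags (def, synonym, xref, ...) are permitted and skipped
  }
  stanzas <- flush(cur)
  if (length(ignored_rel)) {
    warning("ignored relationship types: ",
            paste(sort(unique(ignored_rel)), collapse = ", "), call. = FALSE)
  }
  keep <- !vapply(stanzas, function(s) isTRUE(s$obsolete), logical(1))
  stanzas <- stanzas[keep]
  if (!length(stanzas)) {
    return(ontology(tibble::tibble(id = character(), name = character(),
                                   namespace = character()),
                    stats::setNames(list(), character())))
  }
  ids <- vapply(stanzas, `[[`, character(1), "id")
  terms <- tibble::tibble(
    id = ids,
    name = vapply(stanzas, function(s) s$name %||% "", character(1)),
    namespace = vapply(stanzas, function(s) s$namespace %||% "", character(1))
  )
  parents <- stats::setNames(lapply(stanzas, function(s) {
    # edges pointing at obsolete (now removed) terms are dropped
    intersect(s$parents, ids)
  }), ids)
  ontology(terms, parents)
}

#' Descendant closure of a set of terms
#'
#' Returns the reflexive transitive closure over child edges: the input
#' terms plus every more specialized term reachable from them, each counted
#' once (breadth-first traversal with a visited set, so diamonds in the DAG
#' do not duplicate).
#'
#' @param onto An [ontology()].
#' @param term_ids Character vector of term ids present in `onto`.
#' @return Character vector of term ids (sorted).
#' @export
descendant_closure <- function(onto, term_ids) {
  term_ids <- unique(term_ids)
  unknown <- setdiff(term_ids, onto$terms$id)
  if (length(unknown)) {
    stop("unknown term id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  visited <- new.env(parent = emptyenv())
  queue <- term_ids
  for (id in queue) assign(id, TRUE, envir = visited)
  while (length(queue)) {
    cur <- queue[1L]; queue <- queue[-1L]
    for (ch in onto$children[[cur]]) {
      if (!exists(ch, envir = visited, inherits = FALSE)) {
        assign(ch, TRUE, envir = visited)
        queue <- c(queue, ch)
      }
    }
  }
  sort(ls(visited))
}

#' Find ontology terms whose name matches any keyword
#'
#' Case-insensitive substring match on the term name (synonyms and
#' definitions are not searched). Obsolete terms never enter the ontology
#' object, so they cannot match.
#'
#' @param onto An [ontology()].
#' @param keywords Non-empty character vector of keywords.
#' @return Character vector of matching term ids (sorted).
#' @export
find_terms_by_keyword <- function(onto, keywords) {
  stopifnot(length(keywords) >= 1L)
  nm <- tolower(onto$terms$name)
  hit <- rep(FALSE, length(nm))
  for (kw in tolower(keywords)) {
    hit <- hit | grepl(kw, nm, fixed = TRUE)
  }
  sort(onto$terms$id[hit])
}
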