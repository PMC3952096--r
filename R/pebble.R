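#' Generic rigidity of a body-bar multigraph via the (6,6) pebble game
#'
#' Plays the directed (k = 6, l = 6) pebble game of the body-bar-hinge
#' rigidity paradigm: every node starts with 6 pebbles; a bar is independent
#' iff 7 pebbles can be gathered on its endpoints before insertion, and
#' inserting it consumes one pebble. Rigid components are the maximal
#' "spanned" node sets; after every independent insertion the game re-tests
#' the endpoints, and when 7 pebbles can no longer be gathered the set of
#' nodes reachable from the endpoints is tight and is merged into one
#' component. In a (6,6) framework two tight sets sharing a node have a tight
#' union, so components form a partition of the nodes and are maintained with
#' union-find. The result is independent of edge insertion order.
#'
#' @param graph A `body_bar_graph`.
#' @return Object of class `rigidity_result`: list with `components` (list of
#'   body-id vectors, singletons included), `independent_edges`,
#'   `redundant_edges`, `free_dof` (internal degrees of freedom,
#'   `6 n - 6 - independent` for non-empty graphs), `n_bodies`, `total_mult`.
#' @export
pebble_analyze <- function(graph) {
  n <- graph$n_bodies
  edges <- graph$edges
  if (n == 0) {
    return(structure(list(components = list(), independent_edges = 0L,
                          redundant_edges = 0L, free_dof = 0L,
                          n_bodies = 0L, total_mult = 0L),
                     class = "rigidity_result"))
  }

  st <- list(
    peb = rep(6L, n),
    efrom = integer(0), eto = integer(0),
    adj = lapply(seq_len(n), function(i) integer(0))
  )
  uf <- seq_len(n)

  independent <- 0L
  redundant <- 0L

  for (r in seq_len(nrow(edges))) {
    u <- edges$body_a[r]
    v <- edges$body_b[r]
    for (rep_k in seq_len(edges$mult[r])) {
      if (.uf_find(uf, u) == .uf_find(uf, v)) {
        ## endpoints already inside one tight component: bar is redundant
        redundant <- redundant + 1L
        next
      }
      g <- .pg_gather(st, n, u, v, 7L)
      st <- g$state
      if (!g$ok) {
        redundant <- redundant + 1L
        next
      }
      ## accept: insert directed edge from an endpoint holding a pebble
      tail <- if (st$peb[u] > 0L) u else v
      head <- if (tail == u) v else u
      eid <- length(st$efrom) + 1L
      st$efrom[eid] <- tail
      st$eto[eid] <- head
      st$adj[[tail]] <- c(st$adj[[tail]], eid)
      st$peb[tail] <- st$peb[tail] - 1L
      independent <- independent + 1L

      ## component step: endpoints spanned when 7 pebbles are out of reach
      g2 <- .pg_gather(st, n, u, v, 7L)
      st <- g2$state
      if (!g2$ok) {
        comp <- .pg_component(st, n, u, v)
        root <- .uf_find(uf, u)
        for (w in comp) {
          uf <- .uf_union(uf, root, w)
        }
      }
    }
  }

  comp_id <- vapply(seq_len(n), function(i) .uf_find(uf, i), 0L)
  components <- unname(split(seq_len(n), comp_id))
  components <- components[order(vapply(components, min, 0L))]

  structure(
    list(components = components,
         independent_edges = independent,
         redundant_edges = redundant,
         free_dof = as.integer(6L * n - 6L - independent),
         n_bodies = as.integer(n),
         total_mult = as.integer(sum(edges$mult))),
    class = "rigidity_result"
  )
}

#' @export
print.rigidity_result <- function(x, ...) {
  big <- if (length(x$components) > 0) max(lengths(x$components)) else 0L
  cat("<rigidity_result> ", x$n_bodies, " bodies, free_dof ", x$free_dof,
      ", ", length(x$components), " component(s), largest ", big,
      " bodies, ", x$redundant_edges, " redundant bar(s)\n", sep = "")
  invisible(x)
}

## Gather `need` pebbles onto {u, v}. Pebble searches are depth-first over
## the directed edges; a found pebble is carried back by reversing the path.
## On failure `visited` is the set of nodes reachable from u and v.
.pg_gather <- function(st, n, u, v, need) {
  repeat {
    if (st$peb[u] + st$peb[v] >= need) {
      return(list(ok = TRUE, state = st))
    }
    visited <- rep(FALSE, n)
    visited[c(u, v)] <- TRUE
    parent_edge <- integer(n)
    parent_node <- integer(n)
    stack <- c(u, v)
    found <- 0L
    while (length(stack) > 0) {
      x <- stack[length(stack)]
      stack <- stack[-length(stack)]
      for (e in st$adj[[x]]) {
        y <- st$eto[e]
        if (!visited[y]) {
          visited[y] <- TRUE
          parent_edge[y] <- e
          parent_node[y] <- x
          if (st$peb[y] > 0L) {
            found <- y
            break
          }
          stack <- c(stack, y)
        }
      }
      if (found > 0L) break
    }
    if (found == 0L) {
      return(list(ok = FALSE, state = st, visited = which(visited)))
    }
    ## move the pebble from `found` back to the search root
    w <- found
    st$peb[w] <- st$peb[w] - 1L
    while (parent_node[w] != 0L) {
      e <- parent_edge[w]
      p <- parent_node[w]
      st$adj[[p]] <- st$adj[[p]][st$adj[[p]] != e]
      st$adj[[w]] <- c(st$adj[[w]], e)
      st$efrom[e] <- w
      st$eto[e] <- p
      w <- p
    }
    st$peb[w] <- st$peb[w] + 1L
  }
}

## Maximal tight node set containing u,v right after a failed 7-pebble
## gather: at that moment all 6 reachable pebbles sit on {u, v} and the
## maximal spanned set is {u, v} plus every pebble-free node from which no
## free pebble outside {u, v} can be reached. Computed by a reverse search
## seeded at all pebbled nodes other than u, v.
.pg_component <- function(st, n, u, v) {
  bad <- st$peb > 0L
  bad[c(u, v)] <- FALSE
  ## reverse adjacency: edge tail -> head blocks tail when head is bad
  radj <- lapply(seq_len(n), function(i) integer(0))
  for (e in seq_along(st$efrom)) {
    h <- st$eto[e]
    radj[[h]] <- c(radj[[h]], st$efrom[e])
  }
  frontier <- which(bad)
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (w in frontier) {
      for (t in radj[[w]]) {
        if (!bad[t]) {
          bad[t] <- TRUE
          nxt <- c(nxt, t)
        }
      }
    }
    frontier <- nxt
  }
  comp <- which(!bad & st$peb == 0L)
  sort(unique(c(u, v, comp)))
}

.uf_find <- function(uf, i) {
  while (uf[i] != i) i <- uf[i]
  i
}

.uf_union <- function(uf, a, b) {
  ra <- .uf_find(uf, a)
  rb <- .uf_find(uf, b)
  if (ra != rb) uf[max(ra, rb)] <- min(ra, rb)
  uf
}

#' Size of the largest rigid body
#'
#' Without a mechanical model, returns the size in bodies of the largest
#' rigid component. With a model, returns the atom count of the union of the
#' atoms of the largest component's bodies (the LRB measure used by the
#' mutation score). Ties are broken deterministically towards the component
#' whose smallest body id is smallest.
#'
#' @param result A `rigidity_result`.
#' @param model Optional `critres_model` supplying the body-to-atom map.
#' @return Integer; 0 for an empty graph.
#' @export
largest_rigid_body <- function(result, model = NULL) {
  comps <- result$components
  if (length(comps) == 0) return(0L)
  if (is.null(model)) {
    sizes <- lengths(comps)
  } else {
    sizes <- vapply(comps, function(cc) {
      length(unique(unlist(model$bodies$atoms[cc])))
    }, 0L)
  }
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    mins <- vapply(comps[best], min, 0L)
    best <- best[which.min(mins)]
  }
  as.integer(sizes[best[1]])
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a rigidity result into one row per component
#'
#' @param x A `rigidity_result`.
#' @param ... Unused.
#' @return Tibble with `component`, `n_bodies`, `bodies` (list-column).
#' @export
tidy.rigidity_result <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$components),
    n_bodies = lengths(x$components),
    bodies = x$components
  )
}

#' One-row summary of a rigidity result
#'
#' @param x A `rigidity_result`.
#' @param ... Unused.
#' @export
glance.rigidity_result <- function(x, ...) {
  tibble::tibble(
    n_bodies = x$n_bodies,
    free_dof = x$free_dof,
    independent_edges = x$independent_edges,
    redundant_edges = x$redundant_edges,
    n_components = length(x$components),
    largest_component = if (length(x$components) > 0)
      max(lengths(x$components)) else 0L
  )
}
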