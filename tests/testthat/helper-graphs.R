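## small body-bar graphs used across the rigidity tests

bb_graph <- function(edges, n) {
  structure(list(n_bodies = as.integer(n), edges = edges, trimmed = 0L),
            class = "body_bar_graph")
}

pair_graph <- function(mult) {
  bb_graph(tibble::tibble(body_a = 1L, body_b = 2L,
                          mult = as.integer(mult), kind = "bar"), 2)
}

hinge_ring <- function(k) {
  bb_graph(tibble::tibble(body_a = as.integer(seq_len(k)),
                          body_b = as.integer(c(seq_len(k)[-1], 1L)),
                          mult = 5L, kind = "hinge"), k)
}

sorted_components <- function(x) lapply(x$components, sort)
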