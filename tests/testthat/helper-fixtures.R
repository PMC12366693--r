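# Shared fixtures: small worlds and degenerate demographies built in code.

k_deg <- demicabc::PC_METERS_PER_DEGREE

# world with one cell centered exactly on the zone boundary latitude
boundary_world <- function() {
  world_grid(n_cols = 1, n_rows = 1, cell_size = 1e5,
             origin = c(x = 0, y = 43.2 * k_deg - 0.5e5))
}

# a hand-made two-tip genealogy with both branches of length `len`
two_tip_tree <- function(len, tip_time = 100) {
  structure(list(edges = data.frame(parent = c(3L, 3L), child = c(1L, 2L)),
                 time = c(tip_time, tip_time, tip_time - len),
                 n_tips = 2L, tip_label = c("a.1", "a.2")),
            class = "gene_tree")
}

# single-sample scheme for a 1x1 world db (constant_deme_db)
one_deme_scheme <- function(db, n = 2, generation = NULL, layer = "HG") {
  if (is.null(generation)) generation <- db$T
  ctr <- deme_center(db$world, 1)
  sampling_scheme(data.frame(label = "S", layer = layer, x = ctr$x,
                             y = ctr$y, n = n,
                             mean_age = 40000 - 25 * generation),
                  generations_total = db$T + 1L)
}

# breadth-first reachability over land cells (independent connectivity oracle)
bfs_reachable <- function(world, from) {
  D <- world$n_cols * world$n_rows
  seen <- logical(D)
  land <- as.vector(t(world$land_mask))
  queue <- from
  seen[from] <- TRUE
  while (length(queue)) {
    d <- queue[1]
    queue <- queue[-1]
    col <- (d - 1) %% world$n_cols + 1
    row <- (d - 1) %/% world$n_cols + 1
    for (k in 1:4) {
      nc <- col + c(-1, 1, 0, 0)[k]
      nr <- row + c(0, 0, -1, 1)[k]
      if (nc < 1 || nc > world$n_cols || nr < 1 || nr > world$n_rows) next
      nd <- (nr - 1) * world$n_cols + nc
      if (land[nd] && !seen[nd]) {
        seen[nd] <- TRUE
        queue <- c(queue, nd)
      }
    }
  }
  seen
}
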