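# Small reconstructions built in code, used across the suite.

# soma + straight dendrite along +x, n nodes at equal spacing
straight_recon <- function(length_um = 100, n = 11, d = 0.6, soma_r = 5,
                           axis = c(1, 0, 0), start = 0) {
  axis <- axis / sqrt(sum(axis^2))
  s <- seq(start, start + length_um, length.out = n)
  nodes <- data.frame(id = seq_len(n + 1),
                      type = c(1L, rep.int(3L, n)),
                      x = c(0, s * axis[1]), y = c(0, s * axis[2]),
                      z = c(0, s * axis[3]),
                      r = c(soma_r, rep.int(d / 2, n)),
                      parent = c(-1L, seq_len(n)))
  spn_recon(nodes)
}

# soma with one primary that bifurcates once (Y): segment lengths in um
y_recon <- function(stem = 30, arm = 50, d = 0.6, soma_r = 5) {
  rows <- list(c(1, 1, 0, 0, 0, soma_r, -1))
  id <- 1
  add <- function(x, y, z, r, parent) {
    id <<- id + 1
    rows[[id]] <<- c(id, 3, x, y, z, r, parent)
    id
  }
  last <- 1
  for (s in seq(5, stem, by = 5)) last <- add(s, 0, 0, d / 2, last)
  fork <- last
  for (s in seq(5, arm, by = 5)) last <- add(stem + s, s, 0, d / 2, last)
  last <- fork
  for (s in seq(5, arm, by = 5)) last <- add(stem + s, -s, 0, d / 2, last)
  m <- do.call(rbind, rows)
  spn_recon(data.frame(id = m[, 1], type = m[, 2], x = m[, 3], y = m[, 4],
                       z = m[, 5], r = m[, 6], parent = m[, 7]))
}

# full binary tree of given depth; every segment seg_len long, along +x
# with daughters fanned in y. depth 1 = single segment.
binary_recon <- function(depth = 3, seg_len = 20, d = 0.6, soma_r = 5) {
  rows <- list(c(1, 1, 0, 0, 0, soma_r, -1))
  id <- 1
  add <- function(p, parent) {
    id <<- id + 1
    rows[[id]] <<- c(id, 3, p[1], p[2], p[3], d / 2, parent)
    id
  }
  grow <- function(pos, dir, parent, level) {
    for (k in 1:4) {
      pos <- pos + dir * seg_len / 4
      parent <- add(pos, parent)
    }
    if (level < depth) {
      for (sgn in c(1, -1)) {
        ndir <- dir + sgn * c(0, 0.8 / level, 0)
        ndir <- ndir / sqrt(sum(ndir^2))
        grow(pos, ndir, parent, level + 1)
      }
    }
  }
  grow(c(0, 0, 0), c(1, 0, 0), 1, 1)
  m <- do.call(rbind, rows)
  spn_recon(data.frame(id = m[, 1], type = m[, 2], x = m[, 3], y = m[, 4],
                       z = m[, 5], r = m[, 6], parent = m[, 7]))
}

# uniform cylinder with a negligibly small soma, for analytic cable checks
cylinder_recon <- function(length_um = 300, d = 1, n = 301, soma_r = 0.2) {
  straight_recon(length_um, n = n, d = d, soma_r = soma_r)
}
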