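# Shared fixtures and independent oracles, built in code at test time.

# 2-region, 2-category table: counts [[9,1],[5,5]]
tiny_table <- function() {
  case_table(matrix(c(9, 5, 1, 5), 2, 2,
                    dimnames = list(c("A", "B"), c("k1", "k2"))))
}

# 4 regions on the corners of the unit square
unit_square_map <- function() {
  region_map(c("a", "b", "c", "d"),
             x = c(0, 1, 0, 1), y = c(0, 0, 1, 1))
}

# uniform K-category table over a map
uniform_table <- function(map, per_cell = 1, K = 4) {
  case_table(matrix(per_cell, map$n, K), map = map)
}

# independent window-enumeration oracle: for every center/shape/angle,
# rank regions by the area-preserving elliptic metric (implemented from
# scratch with an explicit rotation matrix), take every prefix whose case
# fraction is admissible, and collect the distinct region sets as keys
brute_force_window_sets <- function(map, cases, msws_frac, shapes, angles) {
  if (!any(shapes == 1)) { shapes <- c(1, shapes); angles <- c(1L, angles) }
  keys <- character(0)
  w <- cases$row_totals
  wtot <- sum(w)
  for (c0 in seq_len(map$n)) {
    for (s in seq_along(shapes)) {
      sh <- shapes[s]
      nang <- if (sh == 1) 1L else angles[s]
      for (a in seq_len(nang) - 1L) {
        th <- a * pi / nang
        Rm <- rbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
        off <- t(Rm %*% t(sweep(map$coords, 2, map$coords[c0, ])))
        d <- sqrt(off[, 1]^2 / sh + off[, 2]^2 * sh)
        ord <- order(d, seq_len(map$n))
        for (k in seq_len(map$n)) {
          if (sum(w[ord[seq_len(k)]]) > msws_frac * wtot + 1e-9) break
          keys <- c(keys, paste(sort(ord[seq_len(k)]), collapse = ","))
        }
      }
    }
  }
  sort(unique(keys))
}

window_keys <- function(w) {
  sort(vapply(w$sets, paste, character(1), collapse = ","))
}

# scenario whose "cluster" has null probabilities: a pure-null generator
null_scenario <- function(map, n_cases = 1000) {
  scan_scenario(map, true_clusters = list(1L),
                p0 = rep(0.25, 4), p_list = list(rep(0.25, 4)),
                n_cases = n_cases)
}
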