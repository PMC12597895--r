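# Independent oracles and small fixtures shared across test files.
# Everything here deliberately uses brute force or closed forms so it stays
# independent of the package's own (indexed / compiled) code paths.

# All-pairs contact search: pairs (i, j), i < j, with
# d(i, j) <= contact_scale * (r_i + r_j).
brute_force_pairs <- function(x, y, r, contact_scale) {
  n <- length(x)
  out <- NULL
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        thr <- contact_scale * (r[i] + r[j])
        if ((x[i] - x[j])^2 + (y[i] - y[j])^2 <= thr^2) {
          out <- rbind(out, c(i, j))
        }
      }
    }
  }
  if (is.null(out)) matrix(integer(0), ncol = 2L) else out
}

# Breadth-first-search connected-component sizes of an undirected graph
# given as an edge matrix over nodes 1..n.
bfs_component_sizes <- function(n, edges) {
  adj <- vector("list", n)
  if (nrow(edges) > 0L) {
    for (k in seq_len(nrow(edges))) {
      i <- edges[k, 1L]; j <- edges[k, 2L]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  seen <- logical(n)
  sizes <- integer(0)
  for (s in seq_len(n)) {
    if (seen[s]) next
    queue <- s
    seen[s] <- TRUE
    size <- 0L
    while (length(queue) > 0L) {
      v <- queue[1L]; queue <- queue[-1L]
      size <- size + 1L
      for (w in adj[[v]]) {
        if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
      }
    }
    sizes <- c(sizes, size)
  }
  sizes
}

# Mean squared displacement of a discrete persistent random walk after n
# steps of length `step`, with direction redrawn each step with probability
# `p` (E[u_i . u_j] = (1 - p)^|i - j|).
prw_msd <- function(n, step, p) {
  q <- 1 - p
  k <- seq_len(n - 1L)
  step^2 * (n + 2 * sum((n - k) * q^k))
}

# A snapshot holding given agents, bypassing the simulation.
make_snapshot <- function(x, y, type, radius = 8, domain = NULL, time = 0) {
  abm_snapshot(data.frame(id = seq_along(x) - 1L, type = type, x = x, y = y,
                          radius = radius),
               time = time, domain = domain)
}

# Minimal single-type configuration for engine-level tests; attack wiring
# points at the only type with rate 0 so no attacks ever fire.
single_type_config <- function(params, duration_min, dt_phen = 6,
                               dt_mech = 0.5, repulsion = 10,
                               save_interval_min = dt_phen) {
  simulation_config(
    types = list(cancer = params),
    attack = attack_params(attack_rate = 0),
    mechanics = mechanics_params(repulsion_strength = repulsion,
                                 dt_mech = dt_mech, dt_phen = dt_phen),
    attacker_type = "cancer", target_type = "cancer",
    duration_min = duration_min, save_interval_min = save_interval_min)
}

# Writes a small AnnData h5ad file using the Python anndata library (an
# independent producer of the container format). Returns the path.
write_h5ad_fixture <- function(path, n = 10L, spatial = TRUE,
                               categorical = TRUE) {
  script <- sprintf('
import anndata as ad, numpy as np, pandas as pd
n = %d
types = ["tumor" if i %% 2 == 0 else "Tcell" for i in range(n)]
col = pd.Categorical(types) if %s else types
obs = pd.DataFrame({"celltype": col}, index=[f"c{i}" for i in range(n)])
A = ad.AnnData(X=np.zeros((n, 2), dtype="float32"), obs=obs)
if %s:
    A.obsm["spatial"] = np.column_stack([np.arange(n, dtype=float),
                                         np.arange(n, dtype=float) * -2.5])
A.write_h5ad(%s)
', n, if (categorical) "True" else "False", if (spatial) "True" else "False",
    deparse(path))
  tmp <- tempfile(fileext = ".py")
  writeLines(script, tmp)
  status <- system2("python", tmp, stdout = FALSE, stderr = FALSE)
  stopifnot(status == 0L)
  path
}
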