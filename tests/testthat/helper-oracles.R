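# Independent oracles used across the suite.

# Exact transportation LP solved by scipy's HiGHS interior/simplex solver,
# through the system python; independent of the package's C++ simplex.
py_emd_oracle <- local({
  script <- NULL
  function(a, b, cost) {
    if (is.null(script)) {
      script <<- tempfile(fileext = ".py")
      writeLines(c(
        "import json, sys",
        "import numpy as np",
        "from scipy.optimize import linprog",
        "d = json.load(open(sys.argv[1]))",
        "a = np.array(d['a']); b = np.array(d['b'])",
        "C = np.array(d['cost'])",
        "n, m = C.shape",
        "rows = []",
        "for i in range(n):",
        "    r = np.zeros((n, m)); r[i, :] = 1; rows.append(r.ravel())",
        "for j in range(m):",
        "    r = np.zeros((n, m)); r[:, j] = 1; rows.append(r.ravel())",
        "res = linprog(C.ravel(), A_eq=np.array(rows),",
        "              b_eq=np.concatenate([a, b]), method='highs')",
        "print(repr(res.fun))"
      ), script)
    }
    fin <- tempfile(fileext = ".json")
    writeLines(jsonlite::toJSON(list(a = a, b = b, cost = cost),
                                digits = NA), fin)
    out <- system2("python", c(script, fin), stdout = TRUE)
    as.numeric(out[length(out)])
  }
})

# Dense-quadrature Brownian-bridge density for a two-fix segment: the
# analytic time integral evaluated with 4000 midpoint points.
bridge_density_oracle <- function(grid, t0, t1, z0, z1, sigma2, d0, d1,
                                  nsteps = 4000) {
  ctr <- list(x = grid$x0 + (seq_len(grid$nx) - 0.5) * grid$cell,
              y = grid$y0 + (seq_len(grid$ny) - 0.5) * grid$cell)
  z <- matrix(0, grid$nx, grid$ny)
  Tt <- t1 - t0
  for (a in (seq_len(nsteps) - 0.5) / nsteps) {
    v <- Tt * a * (1 - a) * sigma2 + (1 - a)^2 * d0^2 + a^2 * d1^2 + 1e-6
    mx <- z0[1] + a * (z1[1] - z0[1])
    my <- z0[2] + a * (z1[2] - z0[2])
    z <- z + outer(dnorm(ctr$x, mx, sqrt(v)), dnorm(ctr$y, my, sqrt(v)))
  }
  z / sum(z)
}

total_variation <- function(p, q) 0.5 * sum(abs(p - q))
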