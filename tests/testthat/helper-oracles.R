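# Independent brute-force references used to check the package's
# implementations. These deliberately follow the textbook definitions
# step by step, not the implementation path.

# BH step-up: sort, m*p/rank, cumulative min from the largest rank
bh_ref <- function(p) {
  m <- length(p)
  o <- order(p)
  val <- m * p[o] / seq_len(m)
  for (i in (m - 1):1) {
    if (m == 1) break
    val[i] <- min(val[i], val[i + 1])
  }
  val <- pmin(val, 1)
  out <- numeric(m)
  out[o] <- val
  out
}

# Holm-Sidak step-down: adj_(i) = max_{j<=i} 1-(1-p_(j))^(m-j+1)
holm_sidak_ref <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- max(vapply(seq_len(i), function(j) {
      1 - (1 - ps[j])^(m - j + 1)
    }, 0))
  }
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# all permutations of 1..n as a matrix (n! x n), built by insertion
all_perms <- function(n) {
  p <- matrix(1L, 1, 1)
  for (k in 2:n) {
    rows <- nrow(p)
    out <- matrix(0L, rows * k, k)
    for (pos in seq_len(k)) {
      block <- (pos - 1) * rows + seq_len(rows)
      if (pos == 1) {
        out[block, ] <- cbind(k, p)
      } else if (pos == k) {
        out[block, ] <- cbind(p, k)
      } else {
        out[block, ] <- cbind(p[, seq_len(pos - 1), drop = FALSE], k,
                              p[, pos:(k - 1), drop = FALSE])
      }
    }
    p <- out
  }
  p
}

# exact two-sided Spearman p by full rank-permutation enumeration
# (no ties assumed); rho distribution via 1 - 6S/(n(n^2-1))
spearman_exact_ref <- function(x, y, perms = NULL) {
  n <- length(x)
  if (is.null(perms)) perms <- all_perms(n)
  r_obs <- cor(rank(x), rank(y))
  base <- seq_len(n)
  s <- rowSums((perms - matrix(base, nrow(perms), n, byrow = TRUE))^2)
  rho_all <- 1 - 6 * s / (n * (n^2 - 1))
  mean(abs(rho_all) >= abs(r_obs) - 1e-12)
}

# exact two-sided signed-rank p by enumerating all 2^n sign patterns
signed_rank_exact_ref <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p_ge <- mean(v_all >= v_obs)
  p_le <- mean(v_all <= v_obs)
  min(1, 2 * min(p_ge, p_le))
}

# hand-made taxa_cor object for topology tests
make_taxa_cor <- function(rho, p, n_samples = 50) {
  structure(list(rho = rho, p = p, n_samples = n_samples,
                 taxa = rownames(rho)),
            class = "taxa_cor")
}

# tiny hand-built fermentation table: 2 donors, values chosen by hand
tiny_ferm <- function() {
  fibers <- c("pectin", "beta_glucan", "fos", "arabinoxylan")
  rows <- list()
  vals <- list(
    d1 = list(acetate = c(2, 4, 6, 8, 10),    # fibers..., mixture
              propionate = c(1, 1, 1, 1, 4),
              butyrate = c(2, 2, 2, 2, 2.2)),
    d2 = list(acetate = c(4, 4, 4, 4, 4),
              propionate = c(0.4, 0.4, 0.4, 0.4, 0.9),
              butyrate = c(3, 3, 3, 3, 1.5))
  )
  for (d in names(vals)) {
    for (a in names(vals[[d]])) {
      v <- vals[[d]][[a]]
      rows[[length(rows) + 1]] <- tibble::tibble(
        donor_id = d, condition = "HC",
        substrate = c(fibers, "mixture"),
        scfa_type = a, concentration_mM = v
      )
    }
  }
  long <- dplyr::bind_rows(rows)
  totals <- long |>
    dplyr::summarise(concentration_mM = sum(concentration_mM),
                     .by = c(donor_id, condition, substrate)) |>
    dplyr::mutate(scfa_type = "total")
  dplyr::bind_rows(long, totals)
}
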