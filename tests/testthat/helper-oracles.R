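# Independent oracles used across the suite. These re-derive expected
# values by brute force or closed form and must stay independent of the
# implementation paths they check.

# truth-table oracle for the LPS structure rules, written directly from the
# biology: lipid IVA backbone -> producer; waaA -> KDO2; lpxL -> 5th chain;
# lpxM/lpxJ -> 6th chain
oracle_classify <- function(genes) {
  has <- function(g) g %in% genes
  backbone <- has("lpxA") && has("lpxB") && has("lpxC") && has("lpxD") && has("lpxK")
  if (!backbone) {
    return(list(encodes_lps = FALSE, kdo2 = FALSE, acylation = "none",
                hexa_routes = character(0)))
  }
  kdo2 <- has("waaA")
  if (!has("lpxL")) {
    return(list(encodes_lps = TRUE, kdo2 = kdo2, acylation = "tetra",
                hexa_routes = character(0)))
  }
  routes <- c("lpxM", "lpxJ")[c(has("lpxM"), has("lpxJ"))]
  if (length(routes) > 0) {
    list(encodes_lps = TRUE, kdo2 = kdo2, acylation = "hexa",
         hexa_routes = routes)
  } else {
    list(encodes_lps = TRUE, kdo2 = kdo2, acylation = "penta",
         hexa_routes = character(0))
  }
}

# plain double-loop KL evaluation of sqrt-JSD for two probability vectors
oracle_sqrt_jsd <- function(a, b) {
  a <- a / sum(a)
  b <- b / sum(b)
  m <- (a + b) / 2
  kl <- function(p, q) {
    s <- 0
    for (i in seq_along(p)) {
      if (p[i] > 0) s <- s + p[i] * log(p[i] / q[i])
    }
    s
  }
  sqrt(kl(a, m) / 2 + kl(b, m) / 2)
}

# exhaustive k-medoids optimum
oracle_pam_objective <- function(d, k) {
  n <- nrow(d)
  combs <- utils::combn(n, k)
  min(apply(combs, 2, function(m) {
    sum(apply(d[m, , drop = FALSE], 2, min))
  }))
}

# small fixed toy distance matrix from 2-D points (two clear clouds)
toy_two_clouds <- function() {
  pts <- rbind(
    c(0, 0), c(0.2, 0.1), c(0.1, -0.1), c(-0.1, 0.2),
    c(10, 10), c(10.2, 9.9), c(9.9, 10.1)
  )
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(paste0("s", 1:7), paste0("s", 1:7))
  d
}

# gene-set shorthand
gs <- function(...) c(...)
backbone5 <- c("lpxA", "lpxB", "lpxC", "lpxD", "lpxK")
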