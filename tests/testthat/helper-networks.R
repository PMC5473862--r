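# Seeded random two-type (L/P) binary networks used by the property tests.
random_lp_network <- function(n_l, n_p, seed, density = 0.4) {
  m <- withr::with_seed(seed, {
    sym <- function(n) {
      x <- matrix(as.numeric(stats::runif(n * n) < density), n, n)
      x[lower.tri(x, diag = TRUE)] <- 0
      x + t(x)
    }
    list(ll = sym(n_l),
         pp = sym(n_p),
         lp = matrix(as.numeric(stats::runif(n_l * n_p) < density), n_l, n_p))
  })
  lnc <- sprintf("l%d", seq_len(n_l))
  prot <- sprintf("p%d", seq_len(n_p))
  dimnames(m$ll) <- list(lnc, lnc)
  dimnames(m$pp) <- list(prot, prot)
  dimnames(m$lp) <- list(lnc, prot)
  hetero_network_from_matrices(list("L|L" = m$ll, "L|P" = m$lp,
                                    "P|P" = m$pp))
}

random_edge_set <- function(n_src, n_tgt, seed, source_type = "L",
                            target_type = "P") {
  withr::with_seed(seed, {
    grid <- expand.grid(source = sprintf("%s%d", tolower(source_type),
                                         seq_len(n_src)),
                        target = sprintf("%s%d", tolower(target_type),
                                         seq_len(n_tgt)),
                        stringsAsFactors = FALSE)
    grid$weight <- stats::runif(nrow(grid))
    edge_set(grid, source_type, target_type)
  })
}

write_tsv_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
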