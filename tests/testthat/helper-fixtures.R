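# Shared fixtures and independent oracles for the test suite.  Oracles are
# deliberately naive (exhaustive enumeration, brute-force scans, quadrature)
# and never share code paths with the implementation they check.

aa20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_records <- function(n, len_range = c(5, 40), gapped = FALSE) {
  seqs <- vapply(seq_len(n), function(i) {
    len <- sample(len_range[1]:len_range[2], 1)
    alpha <- if (gapped) c(aa20, "X", "-") else c(aa20, "X")
    paste(sample(alpha, len, replace = TRUE), collapse = "")
  }, character(1))
  names(seqs) <- sprintf("rec%03d", seq_len(n))
  seqs
}

toy_tree4 <- function() {
  ape::read.tree(text = "((A:0.1,B:0.2):0.15,(C:0.3,D:0.05):0.2);")
}

# Exhaustive-enumeration site likelihood: sums the joint probability over
# every assignment of internal-node states.  Only usable for tiny trees.
enumeration_site_logliks <- function(alignment, tree, model) {
  m <- as.matrix(alignment)
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nn <- tree$Nnode
  Ps <- lapply(tree$edge.length, function(t) vkorcp:::transition_prob(model, t))
  root <- tree$edge[nrow(tree$edge), 1]
  grid <- as.matrix(expand.grid(rep(list(1:20), nn)))
  vapply(seq_len(ncol(m)), function(s) {
    obs <- match(m[tree$tip.label, s], aa20)   # NA = missing
    tot <- 0
    for (g in seq_len(nrow(grid))) {
      st <- function(node) if (node <= ntip) obs[node] else grid[g, node - ntip]
      p <- model$pi[st(root)]
      for (e in seq_len(nrow(tree$edge))) {
        a <- st(tree$edge[e, 1])
        b <- st(tree$edge[e, 2])
        if (is.na(b)) next                     # missing tip: marginalized
        p <- p * Ps[[e]][a, b]
      }
      tot <- tot + p
    }
    log(tot)
  }, numeric(1))
}

# Mixture (+I/+G) enumeration oracle built on the plain enumeration.
enumeration_mixture_logliks <- function(alignment, tree, model) {
  rates <- vkorcp:::model_rates(model)
  percat <- sapply(rates, function(r) {
    tr <- tree
    tr$edge.length <- tr$edge.length * r
    enumeration_site_logliks(alignment, tr, vkorcp:::set_rate_params(model, alpha = NA, p_inv = NA))
  })
  percat <- matrix(percat, ncol = length(rates))
  gm <- log(rowMeans(exp(percat)))
  p_inv <- if (is.na(model$p_inv)) 0 else model$p_inv
  if (p_inv == 0) return(gm)
  m <- as.matrix(alignment)
  inv <- apply(m, 2, function(col) {
    obs <- col[!col %in% c("X", "-")]
    if (length(obs) == 0) return(1)
    if (length(unique(obs)) == 1) return(unname(model$pi[match(obs[1], aa20)]))
    0
  })
  log(p_inv * inv + (1 - p_inv) * exp(gm))
}

# Quadrature oracle for discrete-gamma category means: adaptive integration
# of x * dgamma(x) over each equal-probability quantile bin.
quadrature_gamma_rates <- function(alpha, n_cat) {
  q <- qgamma(seq(0, 1, length.out = n_cat + 1), shape = alpha, rate = alpha)
  q[n_cat + 1] <- Inf
  vapply(seq_len(n_cat), function(k) {
    n_cat * integrate(function(x) x * dgamma(x, shape = alpha, rate = alpha),
                      q[k], q[k + 1], rel.tol = 1e-12)$value
  }, numeric(1))
}

# Independent identity recount for a module alignment: direct character
# comparison of the two residue strings at the stated offset.
recount_identities <- function(mod1, mod2, offset) {
  r1 <- strsplit(mod1$residues, "")[[1]]
  r2 <- strsplit(mod2$residues, "")[[1]]
  count <- 0L
  for (j in seq_along(r2)) {
    i <- j + offset
    if (i >= 1 && i <= length(r1) && r1[i] == r2[j] && r1[i] != "X") {
      count <- count + 1L
    }
  }
  count
}

index_fixture <- function() {
  fa <- read_fasta(system.file("extdata", "index_sequences.fasta",
                               package = "vkorcp"))
  hel <- yaml::read_yaml(system.file("extdata", "index_helices.yaml",
                                     package = "vkorcp"))
  list(vkorc1 = unclass(fa)[["VKORC1_HUMAN"]],
       dsbb = unclass(fa)[["DSBB_ECOLI"]],
       helices = lapply(hel, function(h) lapply(h, function(r) c(r[[1]], r[[2]]))))
}
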