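#' Simulate a random tree, optionally with labeled monophyletic clades
#'
#' Without `clade_spec`, a random bifurcating tree (`ape::rtree`) with
#' uniform branch lengths.  With `clade_spec`, `k` labeled monophyletic
#' groups are generated as random subtrees grafted onto a random backbone,
#' each behind a stem branch of the stated length, so the groups are
#' recoverable as clades of the rooted tree.
#'
#' @param n_taxa Number of leaves (>= 3).
#' @param seed Integer seed (same seed, same newick string).
#' @param clade_spec Optional list with `sizes` (named integer vector of
#'   clade sizes summing to `n_taxa`) and `stem_length`.
#' @return A rooted `phylo` tree; with clades, leaf labels are
#'   `c<label>_t<i>` and the true assignment is in `attr(,"clade_labels")`.
#' @export
simulate_tree <- function(n_taxa, seed, clade_spec = NULL) {
  if (n_taxa < 3L) stop_ctx("n_taxa must be >= 3")
  with_seed(seed, {
    if (is.null(clade_spec)) {
      tr <- ape::rtree(n_taxa, br = function(n) runif(n, 0.05, 0.3))
      tr$tip.label <- sprintf("t%d", seq_len(n_taxa))
      return(tr)
    }
    sizes <- clade_spec$sizes
    if (is.null(names(sizes))) names(sizes) <- as.character(seq_along(sizes))
    if (length(sizes) < 1L) stop_ctx("clade_spec needs at least one clade")
    if (sum(sizes) != n_taxa) {
      stop_ctx("clade sizes sum to %d, not n_taxa = %d", sum(sizes), n_taxa)
    }
    stem <- clade_spec$stem_length %||% 0.5
    subtree_newick <- function(label, size) {
      tips <- sprintf("c%s_t%d", label, seq_len(size))
      if (size == 1L) return(tips)
      tr <- ape::rtree(size, br = function(n) runif(n, 0.05, 0.25))
      tr$tip.label <- tips
      sub(";$", "", ape::write.tree(tr))
    }
    backbone <- if (length(sizes) == 1L) {
      sprintf("(%s:%.6f);", subtree_newick(names(sizes)[1], sizes[[1]]), stem)
    } else {
      bb <- ape::rtree(length(sizes), br = function(n) runif(n, 0.1, 0.4))
      bb$tip.label <- sprintf("PLACEHOLDER%d", seq_along(sizes))
      txt <- ape::write.tree(bb)
      for (i in seq_along(sizes)) {
        sub_txt <- subtree_newick(names(sizes)[i], sizes[[i]])
        txt <- sub(sprintf("PLACEHOLDER%d:", i),
                   sprintf("%s_STEMLEN:", sub_txt), txt, fixed = TRUE)
      }
      # the grafted subtree keeps the backbone pendant edge, extended to the
      # requested stem length
      txt <- gsub("_STEMLEN:[0-9.eE+-]+", sprintf(":%.6f", stem), txt)
      txt
    }
    tr <- ape::read.tree(text = backbone)
    labels <- rep(names(sizes), times = as.integer(sizes))
    ids <- unlist(lapply(names(sizes), function(l) {
      sprintf("c%s_t%d", l, seq_len(sizes[[l]]))
    }))
    attr(tr, "clade_labels") <- stats::setNames(labels, ids)
    tr
  })
}

#' Evolve an alignment along a tree
#'
#' Draws the root from the model's equilibrium frequencies and evolves
#' states down the tree with transition probabilities `exp(Q t r)` per
#' branch, where `r` is the column's rate.  Columns with rate 0 are
#' invariant (identical in all taxa).
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param model A [substitution_model()].
#' @param n_sites Number of columns (>= 1).
#' @param rate_plan Either a numeric vector of per-column rates (0 =
#'   invariant) or a list with `n_invariant` and `alpha` (invariant columns
#'   at random positions, remaining rates drawn from a mean-1 gamma).
#' @param seed Integer seed.
#' @return An [aa_alignment()]; the planted truth (`site_rates`,
#'   `invariant_columns`, `tree`, `seed`) is in `attr(,"truth")`.
#' @export
evolve_alignment <- function(tree, model, n_sites, rate_plan = list(), seed = 1L) {
  if (n_sites < 1L) stop_ctx("n_sites must be >= 1")
  stopifnot(inherits(tree, "phylo"))
  with_seed(seed, {
    if (is.numeric(rate_plan)) {
      rates <- rep_len(rate_plan, n_sites)
    } else {
      n_inv <- rate_plan$n_invariant %||% 0L
      alpha <- rate_plan$alpha %||% model$alpha
      rates <- if (is.na(alpha) || is.null(alpha)) rep(1, n_sites) else {
        rgamma(n_sites, shape = alpha, rate = alpha)
      }
      if (n_inv > 0L) rates[sample.int(n_sites, n_inv)] <- 0
    }
    ntip <- length(tree$tip.label)
    tr <- ape::reorder.phylo(tree, "postorder")
    n_nodes <- ntip + tr$Nnode
    states <- matrix(NA_integer_, n_nodes, n_sites)
    root <- tr$edge[nrow(tr$edge), 1]
    states[root, ] <- sample.int(20L, n_sites, replace = TRUE, prob = model$pi)
    exp_lam <- function(t) exp(model$lambda * t)
    for (e in rev(seq_len(nrow(tr$edge)))) {   # preorder traversal
      parent <- tr$edge[e, 1]
      child <- tr$edge[e, 2]
      t <- tr$edge.length[e]
      # site-specific P rows: prob(child = b | parent = a_s, t * r_s)
      E <- exp(outer(rates * t, model$lambda))            # n_sites x 20
      M <- model$V[states[parent, ], , drop = FALSE] * E  # n_sites x 20
      probs <- M %*% model$Vinv
      probs[probs < 0] <- 0
      states[child, ] <- vapply(seq_len(n_sites), function(s) {
        sample.int(20L, 1L, prob = probs[s, ])
      }, integer(1))
    }
    m <- matrix(.aa_states[states[seq_len(ntip), ]], ntip, n_sites)
    rownames(m) <- tr$tip.label
    aln <- alignment_from_matrix(m)
    attr(aln, "truth") <- list(tree = tree, site_rates = rates,
                               invariant_columns = which(rates == 0),
                               seed = seed)
    aln
  })
}

#' Plant a diagnostic marker and clade-specific insertion blocks
#'
#' The marker overwrites the chosen column: all group rows get the marker
#' state and every other row a disjoint state, making the site a perfect
#' presence/absence determinant.  Each insertion block adds new columns
#' carrying residues in the member clades and gaps everywhere else (the
#' clade-specific insertions seen as "absent segments" from other clades).
#'
#' @param alignment An [aa_alignment()] (typically from
#'   [evolve_alignment()]).
#' @param truth Truth list to update (defaults to the alignment's).
#' @param marker_spec `NULL` or list with `column`, `state`, `group`
#'   (member ids) and optional `out_state`.
#' @param insertion_spec `NULL`, or a list of blocks, each with `clades`
#'   (labels into `truth$clade_labels`), `length`, `after_column`.
#' @param seed Seed for the inserted residues.
#' @return The modified alignment with updated `attr(,"truth")` (fields
#'   `marker` and `insertion_blocks`; column indices in `truth` are shifted
#'   to the post-insertion coordinates).
#' @export
plant_features <- function(alignment, truth = NULL, marker_spec = NULL,
                           insertion_spec = NULL, seed = 1L) {
  alignment <- as_alignment(alignment)
  truth <- truth %||% attr(alignment, "truth") %||% list()
  m <- as.matrix(alignment)

  if (!is.null(marker_spec)) {
    col <- marker_spec$column
    if (col < 1L || col > ncol(m)) stop_ctx("marker column %d out of range", col)
    grp <- marker_spec$group
    missing <- setdiff(grp, rownames(m))
    if (length(missing)) {
      stop_ctx("marker group ids not in alignment: %s",
               paste(missing, collapse = ", "))
    }
    state <- marker_spec$state
    others <- setdiff(rownames(m), grp)
    out_state <- marker_spec$out_state %||% {
      cand <- setdiff(.aa_states, state)
      tab <- table(m[others, col])
      tab <- tab[names(tab) %in% cand]
      if (length(tab)) names(which.max(tab)) else cand[1]
    }
    m[grp, col] <- state
    m[others, col] <- out_state
    truth$marker <- list(column = col, state = state, group = grp,
                         out_state = out_state)
  }

  if (!is.null(insertion_spec)) {
    if (!is.null(insertion_spec$length)) insertion_spec <- list(insertion_spec)
    clade_labels <- truth$clade_labels
    if (is.null(clade_labels)) stop_ctx("insertion planting needs truth$clade_labels")
    # insert right-to-left so earlier block coordinates stay valid
    ord <- order(vapply(insertion_spec, function(b) b$after_column, numeric(1)),
                 decreasing = TRUE)
    blocks <- list()
    with_seed(seed, {
      for (b in insertion_spec[ord]) {
        labs <- as.character(b$clades)
        unknown <- setdiff(labs, unique(clade_labels))
        if (length(unknown)) stop_ctx("unknown clade label(s): %s",
                                      paste(unknown, collapse = ", "))
        members <- names(clade_labels)[clade_labels %in% labs]
        len <- b$length
        at <- b$after_column
        if (at < 1L || at >= ncol(m)) {
          stop_ctx("insertion must be internal (after_column %d)", at)
        }
        block <- matrix("-", nrow(m), len, dimnames = list(rownames(m), NULL))
        block[members, ] <- sample(.aa_states, length(members) * len,
                                   replace = TRUE, prob = .wag_freq)
        m <- cbind(m[, seq_len(at), drop = FALSE], block,
                   m[, (at + 1L):ncol(m), drop = FALSE])
        shift <- function(x) ifelse(x > at, x + len, x)
        if (!is.null(truth$marker)) truth$marker$column <- shift(truth$marker$column)
        if (length(truth$invariant_columns)) {
          truth$invariant_columns <- shift(truth$invariant_columns)
        }
        if (length(truth$site_rates)) {
          truth$site_rates <- append(truth$site_rates, rep(NA_real_, len), after = at)
        }
        blocks <- lapply(blocks, function(b2) {
          b2$col_start <- shift(b2$col_start)
          b2$col_end <- shift(b2$col_end)
          b2
        })
        blocks <- c(blocks, list(list(col_start = at + 1L, col_end = at + len,
                                      length = len, clades = labs,
                                      member_ids = members)))
      }
    })
    # earlier insertions shift later ones' recorded coordinates
    blocks <- blocks[order(vapply(blocks, `[[`, numeric(1), "col_start"))]
    truth$insertion_blocks <- blocks
  }

  out <- alignment_from_matrix(m)
  attr(out, "truth") <- truth
  out
}

#' Derive a circularly permuted partner family
#'
#' Rotates every (ungapped) sequence at `boundary` -- suffix then prefix,
#' as in [half_swap()] -- and applies random substitutions at the expected
#' per-site rate `divergence`, emulating a diverged partner family related
#' by circular permutation.
#'
#' @param alignment Source [aa_alignment()] or `seq_records`.
#' @param truth Truth list to update.
#' @param boundary Rotation point (`1 < boundary < sequence length` for
#'   every sequence).
#' @param divergence Expected fraction of substituted sites in `[0, 1)`.
#' @param seed Integer seed.
#' @return `seq_records` of the partner family (ids prefixed `cp_`) with
#'   updated `attr(,"truth")` recording `cp_boundary`.
#' @export
make_cp_family <- function(alignment, truth = NULL, boundary, divergence = 0.15,
                           seed = 1L) {
  if (divergence < 0 || divergence >= 1) stop_ctx("divergence must be in [0, 1)")
  truth <- truth %||% attr(alignment, "truth") %||% list()
  seqs <- vapply(unclass(as_seq_records(alignment)), degap, character(1))
  lens <- nchar(seqs)
  if (boundary <= 1L || any(boundary >= lens)) {
    stop_ctx("boundary %d outside the ungapped sequence lengths", boundary)
  }
  with_seed(seed, {
    out <- vapply(seqs, function(s) {
      r <- strsplit(half_swap(s, boundary), "")[[1]]
      hit <- runif(length(r)) < divergence
      if (any(hit)) {
        r[hit] <- vapply(r[hit], function(cur) {
          sample(setdiff(.aa_states, cur), 1L)
        }, character(1))
      }
      paste(r, collapse = "")
    }, character(1))
    names(out) <- paste0("cp_", names(seqs))
    rec <- seq_records(out)
    truth$cp_boundary <- as.integer(boundary)
    truth$cp_divergence <- divergence
    attr(rec, "truth") <- truth
    rec
  })
}

as_seq_records <- function(x) {
  if (inherits(x, "seq_records")) x else seq_records(x)
}

#' Toy four-helix bundle coordinates with known contacts
#'
#' Places ideal alpha-helices (1.5 angstrom rise and 100 degrees turn per
#' residue; C-alpha at 2.3 angstrom radius plus one side-chain pseudo-atom
#' at 3.3 angstrom) on the corners of a square of side `spacing`, and
#' computes the true interhelical contact list by exhaustive all-pairs
#' distance enumeration.  A small `jitter` (default 0.25 angstrom normal
#' noise) makes instances differ across seeds.
#'
#' @param n_helices Number of helices (default 4; labels `A`, `B`, ...).
#' @param residues_per_helix Residues per helix.
#' @param spacing Square side in angstrom.
#' @param seed Integer seed.
#' @param cutoff Contact cutoff recorded in the truth.
#' @param jitter Coordinate noise standard deviation in angstrom.
#' @param with_ligand Add a 3-atom HETATM ligand (`UNL`) near the bundle
#'   center and record its true residue contacts.
#' @return List with `atoms` (data frame as from [read_pdb_atoms()]),
#'   `helices` annotation data frame, `sequence`, and `truth` (true
#'   `contacts`, `ligand_contacts`, `cutoff`, `seed`).
#' @export
make_toy_bundle <- function(n_helices = 4L, residues_per_helix = 12L,
                            spacing = 10, seed = 1L, cutoff = 4.5,
                            jitter = 0.25, with_ligand = FALSE) {
  if (spacing <= 0) stop_ctx("spacing must be positive")
  with_seed(seed, {
    corners <- cbind(c(0, 1, 1, 0, 0.5, 1.5, 1.5, 0.5),
                     c(0, 0, 1, 1, 0.5, 0.5, 1.5, 1.5))[seq_len(n_helices), , drop = FALSE] * spacing
    labels <- LETTERS[seq_len(n_helices)]
    three <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
               GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
               LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
               SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
    rows <- list()
    seq_states <- character(0)
    res_counter <- 0L
    for (h in seq_len(n_helices)) {
      for (r in seq_len(residues_per_helix)) {
        res_counter <- res_counter + 1L
        ang <- (r - 1L) * 100 * pi / 180
        z <- (r - 1L) * 1.5
        aa3 <- sample(names(three), 1L)
        seq_states <- c(seq_states, three[[aa3]])
        ca <- c(corners[h, 1] + 2.3 * cos(ang), corners[h, 2] + 2.3 * sin(ang), z)
        cb <- c(corners[h, 1] + 3.3 * cos(ang), corners[h, 2] + 3.3 * sin(ang), z)
        rows[[length(rows) + 1L]] <- data.frame(
          chain = "A", res_seq = res_counter, res_name = aa3,
          atom_name = c("CA", "CB"), element = "C",
          x = c(ca[1], cb[1]), y = c(ca[2], cb[2]), z = c(ca[3], cb[3]),
          het = FALSE, stringsAsFactors = FALSE)
      }
    }
    atoms <- do.call(rbind, rows)
    if (jitter > 0) {
      atoms$x <- atoms$x + rnorm(nrow(atoms), 0, jitter)
      atoms$y <- atoms$y + rnorm(nrow(atoms), 0, jitter)
      atoms$z <- atoms$z + rnorm(nrow(atoms), 0, jitter)
    }
    atoms$x <- round(atoms$x, 3)
    atoms$y <- round(atoms$y, 3)
    atoms$z <- round(atoms$z, 3)
    helices <- data.frame(
      label = labels, chain = "A",
      res_start = (seq_len(n_helices) - 1L) * residues_per_helix + 1L,
      res_end = seq_len(n_helices) * residues_per_helix,
      stringsAsFactors = FALSE)
    if (with_ligand) {
      center <- colMeans(corners)
      anchor <- atoms[atoms$res_seq == 1L & atoms$atom_name == "CB", ]
      lig <- data.frame(
        chain = "A", res_seq = 900L, res_name = "UNL",
        atom_name = c("C1", "C2", "C3"), element = "C",
        x = round(c(anchor$x + 2.5, center[1], center[1] + 1), 3),
        y = round(c(anchor$y, center[2], center[2]), 3),
        z = round(c(anchor$z, 8, 9.5), 3),
        het = TRUE, stringsAsFactors = FALSE)
      atoms <- rbind(atoms, lig)
    }
    truth <- list(
      contacts = brute_force_contacts(atoms, helices, cutoff),
      cutoff = cutoff, seed = seed,
      helix_of = stats::setNames(
        rep(labels, each = residues_per_helix),
        seq_len(n_helices * residues_per_helix)))
    if (with_ligand) {
      truth$ligand_contacts <- brute_force_ligand(atoms, "UNL", cutoff)
    }
    list(atoms = atoms, helices = helices,
         sequence = paste(seq_states, collapse = ""), truth = truth)
  })
}

# Independent exhaustive enumeration of interhelical contacts: plain double
# loop over all heavy-atom pairs, no per-helix indexing shortcuts.
brute_force_contacts <- function(atoms, helices, cutoff) {
  atoms <- atoms[atoms$element != "H" & !atoms$het, , drop = FALSE]
  helix_of <- rep(NA_character_, max(atoms$res_seq))
  for (i in seq_len(nrow(helices))) {
    helix_of[helices$res_start[i]:helices$res_end[i]] <- helices$label[i]
  }
  best <- new.env()
  for (i in seq_len(nrow(atoms))) {
    for (j in seq_len(nrow(atoms))) {
      if (j <= i) next
      ri <- atoms$res_seq[i]; rj <- atoms$res_seq[j]
      hi <- helix_of[ri]; hj <- helix_of[rj]
      if (is.na(hi) || is.na(hj) || hi == hj) next
      d <- sqrt((atoms$x[i] - atoms$x[j])^2 + (atoms$y[i] - atoms$y[j])^2 +
                  (atoms$z[i] - atoms$z[j])^2)
      if (d > cutoff) next
      key <- paste(min(ri, rj), max(ri, rj))
      cur <- mget(key, envir = best, ifnotfound = Inf)[[1]]
      if (d < cur) assign(key, d, envir = best)
    }
  }
  keys <- ls(best)
  if (length(keys) == 0L) {
    return(data.frame(res_i = integer(0), res_j = integer(0),
                      distance = numeric(0)))
  }
  parts <- do.call(rbind, strsplit(keys, " "))
  out <- data.frame(res_i = as.integer(parts[, 1]),
                    res_j = as.integer(parts[, 2]),
                    distance = vapply(keys, get, numeric(1), envir = best))
  out <- out[order(out$res_i, out$res_j), ]
  rownames(out) <- NULL
  out
}

brute_force_ligand <- function(atoms, resname, cutoff) {
  atoms <- atoms[atoms$element != "H", , drop = FALSE]
  lig <- atoms[atoms$het & atoms$res_name == resname, , drop = FALSE]
  prot <- atoms[!atoms$het, , drop = FALSE]
  hits <- integer(0)
  for (i in seq_len(nrow(prot))) {
    for (j in seq_len(nrow(lig))) {
      d <- sqrt((prot$x[i] - lig$x[j])^2 + (prot$y[i] - lig$y[j])^2 +
                  (prot$z[i] - lig$z[j])^2)
      if (d <= cutoff) hits <- c(hits, prot$res_seq[i])
    }
  }
  sort(unique(hits))
}

#' Generate a complete synthetic study bundle
#'
#' Emits every input the pipeline needs, with known ground truth: a
#' five-clade tree, an alignment evolved under WAG+G with planted invariant
#' "catalytic" columns, a planted group-specific marker and a planted
#' animal-style insertion block, a circularly permuted partner family, and a
#' toy helix bundle with a bound ligand.  A self-audit verifies every
#' planted feature against the emitted data before anything is written.
#'
#' @param config Optional list overriding the defaults (see Details).
#' @param seed Master seed; all sub-generators derive their own streams.
#' @param dir Optional output directory; when given, writes `msa.fasta`,
#'   `tree.nwk`, `partner.fasta`, `bundle.pdb`, `helices.yaml`,
#'   `clades.tsv` and `truth.json`.
#' @details Defaults: 60 taxa in 5 clades (18/7/7/10/18), 160 evolved sites
#'   (gamma alpha 0.8), 5 invariant catalytic columns, one 6-member marker
#'   group spanning clades 1 and 5 (marker state `C`), one 13-column
#'   insertion shared by clades 2--4, a CP partner at 15\% divergence
#'   rotated at half the core length, and a 4-helix toy bundle.
#' @return List with `alignment`, `tree`, `partner`, `bundle`, `clades`
#'   (assignment vector), and `truth`.
#' @export
generate_study_bundle <- function(config = list(), seed = 1L, dir = NULL) {
  cfg <- utils::modifyList(list(
    clade_sizes = c("1" = 18L, "2" = 7L, "3" = 7L, "4" = 10L, "5" = 18L),
    n_sites = 160L, n_invariant = 5L, alpha = 0.8, stem_length = 0.5,
    marker_state = "C", marker_group_size = 6L,
    insertion_length = 13L, insertion_clades = c("2", "3", "4"),
    cp_divergence = 0.15, bundle_spacing = 10, with_ligand = TRUE
  ), config)
  if (length(cfg$clade_sizes) == 0L) stop_ctx("config needs at least one clade")
  n_taxa <- sum(cfg$clade_sizes)

  tree <- simulate_tree(n_taxa, derive_seed(seed, 1L),
                        clade_spec = list(sizes = cfg$clade_sizes,
                                          stem_length = cfg$stem_length))
  clade_labels <- attr(tree, "clade_labels")
  model <- substitution_model("WAG", alpha = cfg$alpha)
  aln <- evolve_alignment(tree, model, cfg$n_sites,
                          rate_plan = list(n_invariant = cfg$n_invariant,
                                           alpha = cfg$alpha),
                          seed = derive_seed(seed, 2L))
  truth <- attr(aln, "truth")
  truth$clade_labels <- clade_labels

  # marker group: members drawn from clades 1 and 5 (when present)
  pool_labels <- intersect(c("1", "5"), unique(clade_labels))
  if (length(pool_labels) == 0L) pool_labels <- unique(clade_labels)[1]
  pool <- names(clade_labels)[clade_labels %in% pool_labels]
  grp <- with_seed(derive_seed(seed, 3L), {
    sort(sample(pool, min(cfg$marker_group_size, length(pool))))
  })
  marker_col <- with_seed(derive_seed(seed, 4L), {
    variable <- setdiff(seq_len(cfg$n_sites), truth$invariant_columns)
    sample(variable[variable > 5 & variable < cfg$n_sites - 5], 1L)
  })
  insert_at <- with_seed(derive_seed(seed, 5L), {
    sample(setdiff(30:(cfg$n_sites - 30L), (marker_col - 14L):(marker_col + 1L)), 1L)
  })
  aln <- plant_features(
    aln, truth,
    marker_spec = list(column = marker_col, state = cfg$marker_state, group = grp),
    insertion_spec = list(clades = cfg$insertion_clades,
                          length = cfg$insertion_length,
                          after_column = insert_at),
    seed = derive_seed(seed, 6L))
  truth <- attr(aln, "truth")

  boundary <- floor(cfg$n_sites / 2)
  partner <- make_cp_family(aln, truth, boundary = boundary,
                            divergence = cfg$cp_divergence,
                            seed = derive_seed(seed, 7L))
  truth <- attr(partner, "truth")

  bundle <- make_toy_bundle(spacing = cfg$bundle_spacing,
                            seed = derive_seed(seed, 8L),
                            with_ligand = cfg$with_ligand)
  truth$bundle <- bundle$truth
  truth$seed <- seed
  truth$config <- cfg

  audit_bundle(aln, tree, partner, bundle, truth)

  out <- list(alignment = aln, tree = tree, partner = partner, bundle = bundle,
              clades = clade_labels, truth = truth)
  if (!is.null(dir)) write_bundle(out, dir)
  out
}

# Verify every planted feature against the emitted data; stops on any
# inconsistency.
audit_bundle <- function(aln, tree, partner, bundle, truth) {
  m <- as.matrix(aln)
  if (!setequal(rownames(m), tree$tip.label)) {
    stop_ctx("bundle audit: alignment ids and tree leaves differ")
  }
  for (col in truth$invariant_columns) {
    if (length(unique(m[, col])) != 1L) {
      stop_ctx("bundle audit: planted invariant column %d is not constant", col)
    }
  }
  mk <- truth$marker
  grp_states <- unique(m[mk$group, mk$column])
  out_states <- unique(m[setdiff(rownames(m), mk$group), mk$column])
  if (!identical(grp_states, mk$state) || mk$state %in% out_states) {
    stop_ctx("bundle audit: marker column %d is not a perfect determinant", mk$column)
  }
  for (b in truth$insertion_blocks) {
    cols <- b$col_start:b$col_end
    inside <- m[b$member_ids, cols, drop = FALSE]
    outside <- m[setdiff(rownames(m), b$member_ids), cols, drop = FALSE]
    if (any(inside == "-") || any(outside != "-")) {
      stop_ctx("bundle audit: insertion block %d-%d has wrong gap structure",
               b$col_start, b$col_end)
    }
  }
  if (length(partner) != nrow(m)) {
    stop_ctx("bundle audit: partner family size mismatch")
  }
  bc <- brute_force_contacts(bundle$atoms, bundle$helices, bundle$truth$cutoff)
  if (!isTRUE(all.equal(bc[c("res_i", "res_j")],
                        bundle$truth$contacts[c("res_i", "res_j")]))) {
    stop_ctx("bundle audit: stored contact truth disagrees with enumeration")
  }
  invisible(TRUE)
}

write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(bundle$alignment, file.path(dir, "msa.fasta"))
  write_newick(bundle$tree, file.path(dir, "tree.nwk"))
  write_fasta(bundle$partner, file.path(dir, "partner.fasta"))
  write_pdb_atoms(bundle$bundle$atoms, file.path(dir, "bundle.pdb"))
  yaml::write_yaml(lapply(seq_len(nrow(bundle$bundle$helices)), function(i) {
    as.list(bundle$bundle$helices[i, ])
  }), file.path(dir, "helices.yaml"))
  utils::write.table(
    data.frame(id = names(bundle$clades), clade = unname(bundle$clades)),
    file.path(dir, "clades.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- bundle$truth
  truth$tree <- ape::write.tree(truth$tree)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
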