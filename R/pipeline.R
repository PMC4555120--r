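#' Run the analysis pipeline end to end
#'
#' Orchestrates the stages -- curation, tree building with bootstrap
#' supports, conservation grading, clade scans, structural contacts and
#' circular-permutation detection -- over a configuration list (or YAML
#' file), writing per-stage outputs and a JSON run manifest (inputs,
#' parameters, seeds, output checksums) into `out_dir`.  Stages can be
#' skipped; a stage failure aborts with the failing stage named.
#'
#' @param config A list or path to a YAML file.  Recognized fields:
#'   `msa` (path to aligned FASTA, required unless `synthetic = TRUE`),
#'   `synthetic` (generate a study bundle instead of reading inputs),
#'   `seed`, `ref_id`, `span` (`c(start, end)`), `motifs`,
#'   `outgroup`, `clade_seeds` (named list), `marker_group`,
#'   `pdb`, `helices` (path to YAML), `cutoff`, `cp_partner` (FASTA path),
#'   `bootstrap_reps`, `stages` (character subset of
#'   `c("curate","tree","conserve","clades","contacts","cp")`).
#' @param out_dir Output directory.
#' @return Invisibly, a list with the per-stage results and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop_ctx("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(list(
    seed = 1L, cutoff = 4.5, bootstrap_reps = 100L,
    stages = c("curate", "tree", "conserve", "clades", "contacts", "cp")
  ), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = cfg$seed, stages = cfg$stages, parameters = cfg,
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  results <- list()
  stage <- function(name, expr) {
    if (!name %in% cfg$stages) return(invisible(NULL))
    tryCatch(force(expr),
             error = function(e) stop_ctx("stage '%s' failed: %s", name,
                                          conditionMessage(e)))
  }

  # input acquisition (validated up front, before any stage runs)
  if (isTRUE(cfg$synthetic)) {
    bundle <- generate_study_bundle(cfg$bundle_config %||% list(),
                                    seed = cfg$seed,
                                    dir = file.path(out_dir, "synthetic"))
    aln <- bundle$alignment
    atoms <- bundle$bundle$atoms
    helices <- bundle$bundle$helices
    partner <- bundle$partner
    cfg$clade_seeds <- cfg$clade_seeds %||%
      lapply(split(names(bundle$clades), unname(bundle$clades)), `[`, 1L)
    cfg$marker_group <- cfg$marker_group %||% bundle$truth$marker$group
    results$synthetic_truth <- bundle$truth
  } else {
    for (f in c("msa", "pdb", "helices", "cp_partner")) {
      if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
        stop_ctx("configured input '%s' does not exist: %s", f, cfg[[f]])
      }
    }
    if (is.null(cfg$msa)) stop_ctx("config needs 'msa' (or synthetic = TRUE)")
    aln <- read_fasta(cfg$msa, aligned = TRUE)
    atoms <- if (!is.null(cfg$pdb)) read_pdb_atoms(cfg$pdb)
    helices <- if (!is.null(cfg$helices)) {
      do.call(rbind, lapply(yaml::read_yaml(cfg$helices), as.data.frame))
    }
    partner <- if (!is.null(cfg$cp_partner)) read_fasta(cfg$cp_partner)
  }

  stage("curate", {
    span <- cfg$span
    cur <- cull_redundant(aln, required_motifs = cfg$motifs,
                          ref_id = cfg$ref_id,
                          start = if (!is.null(span)) span[1],
                          end = if (!is.null(span)) span[2])
    if (!is.null(cfg$ref_id) && !is.null(span)) {
      cur <- truncate_to_region(cur, cfg$ref_id, span[1], span[2])
    }
    removals <- attr(cur, "removals") %||%
      data.frame(id = character(0), reason = character(0))
    utils::write.table(removals, file.path(out_dir, "removals.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_fasta(cur, file.path(out_dir, "curated.fasta"))
    indels <- census_indels(cur)
    utils::write.table(indels[setdiff(names(indels), "member_ids")],
                       file.path(out_dir, "indels.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    results$curated <- cur
    aln <- cur
  })

  model <- substitution_model("WAG", alpha = 1)
  stage("tree", {
    tr0 <- nj_tree(ml_distance_matrix(aln, model))
    est <- estimate_rate_params(aln, tr0, model)
    model <- est$model
    tr <- bootstrap_supports(aln, cfg$bootstrap_reps, seed = cfg$seed,
                             model = model)
    if (!is.null(cfg$outgroup)) tr <- root_with_outgroup(tr, cfg$outgroup)
    write_newick(tr, file.path(out_dir, "tree.nwk"))
    results$tree <- tr
  })

  stage("conserve", {
    if (is.null(results$tree)) stop_ctx("needs the tree stage")
    prof <- conservation_profile(aln, results$tree, model, ref_id = cfg$ref_id)
    utils::write.table(prof, file.path(out_dir, "conservation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    results$conservation <- prof
  })

  stage("clades", {
    if (is.null(results$tree)) stop_ctx("needs the tree stage")
    out <- list()
    if (!is.null(cfg$clade_seeds)) {
      asg <- clade_partition(results$tree, cfg$clade_seeds)
      out$assignment <- asg
      utils::write.table(
        data.frame(id = names(asg), clade = unname(unclass(asg))),
        file.path(out_dir, "clades.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    }
    out$conserved <- fully_conserved_sites(aln, ref_id = cfg$ref_id)
    utils::write.table(out$conserved, file.path(out_dir, "conserved_sites.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(cfg$marker_group)) {
      out$markers <- single_site_markers(aln, cfg$marker_group,
                                         ref_id = cfg$ref_id)
      utils::write.table(out$markers, file.path(out_dir, "markers.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    results$clades <- out
  })

  stage("contacts", {
    if (is.null(atoms) || is.null(helices)) return(invisible(NULL))
    cs <- interhelical_contacts(atoms, helices, cutoff = cfg$cutoff)
    utils::write.table(cs, file.path(out_dir, "contacts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    results$contacts <- cs
  })

  stage("cp", {
    if (is.null(partner)) return(invisible(NULL))
    ref <- degap(unclass(aln)[[1]])
    pr <- unclass(partner)[[1]]
    cp <- find_cp_offset(ref, pr)
    utils::write.table(data.frame(offset = cp$offset, score = cp$score),
                       file.path(out_dir, "cp_offset.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    results$cp <- cp
  })

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  manifest$outputs <- lapply(files, function(f) {
    list(path = sub(paste0("^", out_dir, "/?"), "", f),
         md5 = unname(tools::md5sum(f)))
  })
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  results$manifest <- manifest
  invisible(results)
}
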