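#' Read a primer table
#'
#' Reads a tab-separated primer table with columns `target_genus`,
#' `oligo_name`, `sequence`, and optionally `tm` and `length` (the layout
#' in which LAMP assay sets are published: one row per oligo, composites
#' as full FIP/BIP sequences). Roles are inferred from oligo-name
#' prefixes.
#'
#' @param path Path to a TSV file with a header row.
#' @return Data frame with an added `role` column (`NA` for
#'   unrecognized prefixes).
#' @export
read_primer_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("target_genus", "oligo_name", "sequence")
  if (!all(need %in% names(df)))
    stop("primer TSV must have columns: ", paste(need, collapse = ", "))
  df$sequence <- toupper(gsub("\\s", "", df$sequence))
  df$role <- vapply(df$oligo_name, .infer_role, "")
  df
}

#' Write designed primer sets as a primer table
#'
#' @param sets List of [lamp_primer_set] objects.
#' @param path Output TSV path.
#' @param conditions A [thermo_conditions()] object for reported Tm.
#' @return `path`, invisibly.
#' @export
write_primer_tsv <- function(sets, path, conditions = thermo_conditions()) {
  rows <- list()
  for (si in seq_along(sets)) {
    set <- sets[[si]]
    tag <- if (nzchar(set$genus)) set$genus else paste0("set", si)
    add <- function(name, seq, tm) {
      rows[[length(rows) + 1L]] <<- data.frame(
        target_genus = set$genus, oligo_name = name, sequence = seq,
        tm = round(tm, 1), length = nchar(seq), stringsAsFactors = FALSE)
    }
    add(paste0("F3_", tag), set$primers$F3$seq, set$primers$F3$tm)
    if (!is.null(set$primers$FL))
      add(paste0("FL_", tag), set$primers$FL$seq, set$primers$FL$tm)
    add(paste0("FIP_", tag), set$fip, melting_temperature(set$fip, conditions))
    add(paste0("B3_", tag), set$primers$B3$seq, set$primers$B3$tm)
    if (!is.null(set$primers$BL))
      add(paste0("BL_", tag), set$primers$BL$seq, set$primers$BL$tm)
    add(paste0("BIP_", tag), set$bip, melting_temperature(set$bip, conditions))
  }
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' Materializes every tunable of the pipeline in one list: design
#' constraint windows, thermodynamic conditions, specificity rules,
#' consensus thresholds and seeds. Any element can be overridden via a
#' YAML or JSON config file ([load_run_config()]) or an override list.
#'
#' @return Nested configuration list.
#' @export
default_run_config <- function() {
  list(constraints = unclass(design_constraints()),
       thermo = unclass(thermo_conditions()),
       specificity = unclass(specificity_rules()),
       consensus = list(threshold = 0.8, min_len = 40L, max_gap_frac = 0.1,
                        min_base_frac = 0.2),
       design = list(max_sets = 3L, add_loops = TRUE),
       phylo = list(n_replicates = 500L),
       seed = 1L)
}

#' Load a pipeline configuration file
#'
#' Reads a YAML (or JSON) config and merges it over
#' [default_run_config()]; unknown keys are an error so typos cannot
#' silently fall back to defaults.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file, or `NULL` for pure
#'   defaults.
#' @return Configuration list.
#' @export
load_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  merge_into <- function(base, over, where) {
    for (k in names(over)) {
      if (!k %in% names(base))
        stop("unknown config key: ", paste(c(where, k), collapse = "$"))
      base[[k]] <- if (is.list(base[[k]]) && is.list(over[[k]]))
        merge_into(base[[k]], over[[k]], c(where, k))
      else over[[k]]
    }
    base
  }
  merge_into(cfg, user, character(0))
}

.cfg_objects <- function(config) {
  list(constraints = do.call(design_constraints, config$constraints),
       conditions = do.call(thermo_conditions, config$thermo),
       rules = do.call(specificity_rules, config$specificity))
}

.write_manifest <- function(out_dir, stage, config, extra = list()) {
  manifest <- c(list(stage = stage,
                     package_version = as.character(utils::packageVersion("lampgen")),
                     config = config), extra)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run the design stage: alignment to primer sets
#'
#' Profiles an aligned marker-gene FASTA, extracts conserved regions above
#' the identity threshold, emits a degenerate consensus per region, and
#' designs LAMP primer sets on each consensus until sets are found.
#' Deterministic given input and configuration. Artifacts written to
#' `out_dir`: `consensus.fasta`, `primers.tsv`, `audit.tsv`,
#' `manifest.json`.
#'
#' @param aligned_fasta Path to an aligned FASTA (pipe-delimited headers).
#' @param out_dir Output directory (created if needed).
#' @param config Configuration list from [load_run_config()].
#' @param genus Genus label for the designed sets (default: modal genus
#'   label of the alignment).
#' @return List with `sets`, `regions`, `consensus` (invisible); exit
#'   semantics for the CLI: no feasible set is reported via the
#'   `diagnostic` attribute on an empty `sets` list.
#' @export
run_design <- function(aligned_fasta, out_dir, config = default_run_config(),
                       genus = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  obj <- .cfg_objects(config)
  recs <- read_fasta(aligned_fasta, aligned = TRUE)
  aln <- multi_alignment(recs)
  if (is.null(genus)) {
    g <- recs$genus[!is.na(recs$genus)]
    genus <- if (length(g)) names(sort(table(g), decreasing = TRUE))[1L] else ""
  }
  profiles <- column_profiles(aln)
  regions <- conserved_regions(profiles,
                               threshold = config$consensus$threshold,
                               min_len = config$consensus$min_len,
                               max_gap_frac = config$consensus$max_gap_frac)
  cons <- vapply(seq_len(nrow(regions)), function(i)
    degenerate_consensus(aln, c(regions$start[i], regions$end[i]),
                         min_base_frac = config$consensus$min_base_frac), "")
  if (length(cons)) {
    write_fasta(seq_records(
      id = sprintf("consensus_%02d_%d_%d", seq_along(cons),
                   regions$start + 1L, regions$end),
      seq = cons, genus = genus), file.path(out_dir, "consensus.fasta"))
  }
  sets <- list(); diagnostics <- character(0)
  for (i in seq_along(cons)) {
    roles <- c("F3", "F2", "F1c", "B1c", "B2", "B3")
    cands <- lapply(stats::setNames(roles, roles), function(r)
      enumerate_candidates(cons[i], r, obj$constraints, obj$conditions))
    found <- assemble_sets(cands, obj$constraints, obj$conditions,
                           max_sets = config$design$max_sets, genus = genus)
    if (length(found) == 0L) {
      diagnostics <- c(diagnostics, sprintf("region %d: %s", i,
                                            attr(found, "diagnostic")))
      next
    }
    if (isTRUE(config$design$add_loops))
      found <- lapply(found, add_loop_primers, consensus = cons[i],
                      constraints = obj$constraints, conditions = obj$conditions)
    sets <- c(sets, found)
  }
  if (length(sets)) {
    write_primer_tsv(sets, file.path(out_dir, "primers.tsv"), obj$conditions)
    audits <- lapply(sets, audit_set, constraints = obj$constraints,
                     conditions = obj$conditions)
    audit_df <- do.call(rbind, lapply(seq_along(audits), function(i) {
      df <- as.data.frame(audits[[i]]); df$set <- i; df
    }))
    utils::write.table(audit_df, file.path(out_dir, "audit.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  .write_manifest(out_dir, "design", config,
                  list(input = basename(aligned_fasta),
                       n_regions = nrow(regions), n_sets = length(sets),
                       diagnostics = diagnostics))
  out <- list(sets = sets, regions = regions, consensus = cons,
              diagnostics = diagnostics)
  if (length(sets) == 0L)
    attr(out, "diagnostic") <- paste(diagnostics, collapse = "; ")
  invisible(out)
}

#' Run the audit stage on a published primer table
#'
#' Recomputes per-primer statistics for every set in a primer TSV and
#' writes a violation report. Rows with unrecognized oligo-name prefixes
#' are skipped with a warning.
#'
#' @param primers_tsv Path to a primer table ([read_primer_tsv()] layout).
#' @param out_dir Output directory.
#' @param config Configuration list.
#' @return Data frame of per-primer audit rows across all sets
#'   (invisible).
#' @export
run_audit <- function(primers_tsv, out_dir, config = default_run_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  obj <- .cfg_objects(config)
  df <- read_primer_tsv(primers_tsv)
  skipped <- df$oligo_name[is.na(df$role)]
  for (s in skipped) warning("unknown role prefix, skipping: ", s)
  df <- df[!is.na(df$role), , drop = FALSE]
  out <- list()
  for (g in unique(df$target_genus)) {
    sub <- df[df$target_genus == g, , drop = FALSE]
    primers <- stats::setNames(sub$sequence, sub$oligo_name)
    aud <- audit_set(primers, obj$constraints, obj$conditions)
    audf <- as.data.frame(aud)
    audf$target_genus <- g
    if (nrow(sub) && "length" %in% names(sub)) {
      audf$printed_length <- sub$length[match(audf$name, sub$oligo_name)]
      audf$printed_tm <- if ("tm" %in% names(sub))
        sub$tm[match(audf$name, sub$oligo_name)] else NA_real_
    }
    out[[g]] <- audf
  }
  report <- do.call(rbind, out)
  rownames(report) <- NULL
  utils::write.table(report, file.path(out_dir, "audit.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  .write_manifest(out_dir, "audit", config,
                  list(input = basename(primers_tsv),
                       n_primers = nrow(df), n_skipped = length(skipped),
                       total_violations = sum(report$n_violations)))
  invisible(report)
}

#' Run the specificity screen stage
#'
#' Screens each designed set against a labelled FASTA database and writes
#' hit tables and the per-genus call matrix.
#'
#' @param sets List of [lamp_primer_set] objects.
#' @param db_fasta Path to a FASTA database with genus labels in headers.
#' @param out_dir Output directory.
#' @param config Configuration list.
#' @return List of specificity matrices, one per set (invisible).
#' @export
run_screen <- function(sets, db_fasta, out_dir, config = default_run_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  obj <- .cfg_objects(config)
  db <- read_fasta(db_fasta)
  mats <- lapply(sets, function(set)
    specificity_matrix(set, db, obj$constraints, obj$rules))
  tab <- do.call(rbind, lapply(seq_along(mats), function(i) {
    m <- as.data.frame(mats[[i]])
    m$set <- i; m$target_genus <- attr(mats[[i]], "target_genus")
    m$specific <- attr(mats[[i]], "specific")
    m
  }))
  utils::write.table(tab, file.path(out_dir, "specificity.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  .write_manifest(out_dir, "screen", config,
                  list(input = basename(db_fasta), n_sets = length(sets),
                       n_subjects = nrow(db)))
  invisible(mats)
}

#' Run the phylogeny stage
#'
#' Complete deletion, Jukes-Cantor distances, neighbour-joining and
#' bootstrap, writing the annotated tree as Newick and the distance
#' matrix as TSV.
#'
#' @param aligned_fasta Path to an aligned FASTA.
#' @param out_dir Output directory.
#' @param config Configuration list (`phylo$n_replicates`, `seed`).
#' @return The annotated `phylo` tree (invisible).
#' @export
run_phylo <- function(aligned_fasta, out_dir, config = default_run_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  aln <- complete_deletion(multi_alignment(read_fasta(aligned_fasta,
                                                      aligned = TRUE)))
  tree <- bootstrap_support(aln, n_replicates = config$phylo$n_replicates,
                            seed = config$seed)
  writeLines(write_newick(tree), file.path(out_dir, "tree.nwk"))
  d <- jc_distance_matrix(aln)
  utils::write.table(data.frame(id = rownames(d), d, check.names = FALSE),
                     file.path(out_dir, "distances.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  .write_manifest(out_dir, "phylo", config,
                  list(input = basename(aligned_fasta),
                       n_sequences = nrow(aln$records),
                       n_positions = aln$length,
                       total_branch_length = total_branch_length(tree)))
  invisible(tree)
}

#' Run the full synthetic pipeline end to end
#'
#' Simulates an ORF catalogue and a marker-gene alignment, screens for
#' domain-unique orthologues, extracts conserved consensus regions,
#' designs LAMP primer sets on a planted feasible template, screens them
#' against a simulated target database, and builds the bootstrap
#' phylogeny — the whole workflow on data with known ground truth.
#' Deterministic given `config$seed`; a rerun writes byte-identical
#' primer and tree artifacts.
#'
#' @param out_dir Output directory.
#' @param config Configuration list.
#' @return List with the stage results (invisible).
#' @export
run_synthetic_pipeline <- function(out_dir, config = default_run_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  obj <- .cfg_objects(config)
  seed <- config$seed
  orf <- simulate_orf_catalog(n_orfs = 600L, n_kos = 40L,
                              frac_archaea_unique = 0.25, seed = seed)
  kos <- unique_domain_kos(orf$catalog, "Archaea")
  sim <- simulate_marker_alignment(n_genera = 4L, seqs_per_genus = 4L,
                                   length = 1200L, within_identity = 0.95,
                                   between_identity = 0.75,
                                   n_conserved_windows = 2L, window_len = 220L,
                                   seed = seed)
  aln_path <- file.path(out_dir, "marker_alignment.fasta")
  write_fasta(sim$alignment$records, aln_path)
  profiles <- column_profiles(sim$alignment)
  regions <- conserved_regions(profiles, threshold = config$consensus$threshold,
                               min_len = config$consensus$min_len,
                               max_gap_frac = config$consensus$max_gap_frac)
  tpl <- simulate_lamp_template(obj$constraints, obj$conditions, seed = seed)
  roles <- c("F3", "F2", "F1c", "B1c", "B2", "B3")
  cands <- lapply(stats::setNames(roles, roles), function(r)
    enumerate_candidates(tpl$consensus, r, obj$constraints, obj$conditions))
  sets <- assemble_sets(cands, obj$constraints, obj$conditions,
                        max_sets = 1L, genus = "Genus01")
  screen <- NULL
  if (length(sets)) {
    write_primer_tsv(sets, file.path(out_dir, "primers.tsv"), obj$conditions)
    db <- simulate_target_db(sets[[1L]], n_on_target = 2L, n_off_target = 4L,
                             decoy_divergence = 0.3, seed = seed)
    db_path <- file.path(out_dir, "target_db.fasta")
    write_fasta(db$db, db_path)
    screen <- specificity_matrix(sets[[1L]], db$db, obj$constraints, obj$rules)
  }
  phylo_aln <- complete_deletion(sim$alignment)
  tree <- bootstrap_support(phylo_aln, n_replicates = min(100L,
                                                          config$phylo$n_replicates),
                            seed = seed)
  writeLines(write_newick(tree), file.path(out_dir, "tree.nwk"))
  .write_manifest(out_dir, "synthetic_pipeline", config,
                  list(n_unique_kos = length(kos),
                       n_conserved_regions = nrow(regions),
                       n_sets = length(sets),
                       specific = if (!is.null(screen)) attr(screen, "specific")
                       else NA))
  invisible(list(unique_kos = kos, regions = regions, sets = sets,
                 screen = screen, tree = tree))
}
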