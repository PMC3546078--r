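# Multi-model PDB input/output and the ground-truth table.
#
# Files use chains A (strand I) and B (strand II), 1-based residue
# numbering per chain in 5'->3' order, residue names DA/DC/DG/DT and
# standard nucleic-acid atom names.  Internally pairs are indexed along
# strand I; chain B residue j corresponds to pair n + 1 - j.

#' @noRd
pdb_rows <- function(duplex) {
  a <- duplex$atoms
  n <- duplex$n_pairs
  chain <- ifelse(a$strand == "I", "A", "B")
  resseq <- ifelse(a$strand == "I", a$pair, n + 1 - a$pair)
  ord <- order(chain, resseq)
  data.frame(a[ord, , drop = FALSE], chain = chain[ord],
             resseq = resseq[ord])
}

#' Write an ensemble (or single duplex) as multi-model PDB
#'
#' @param x A `trajectory_ensemble`, a list of `duplex` frames or a
#'   single `duplex`.
#' @param path Output file; for an ensemble with several runs, one file
#'   per run is written with a `_run<k>` suffix.
#' @param run For ensembles: which run(s) to write (default all).
#' @return Invisibly, the path(s) written.
#' @export
write_pdb <- function(x, path, run = NULL) {
  frames_of <- function(r) {
    nf <- dim(x$runs[[r]])[3]
    lapply(seq_len(nf), function(f) get_frame(x, r, f))
  }
  if (inherits(x, "trajectory_ensemble")) {
    runs <- if (is.null(run)) seq_along(x$runs) else run
    paths <- character(length(runs))
    for (k in seq_along(runs)) {
      p <- if (length(runs) == 1) path else {
        sub("(\\.pdb)?$", sprintf("_run%d.pdb", runs[k]), path)
      }
      write_pdb_frames(frames_of(runs[k]), p)
      paths[k] <- p
    }
    return(invisible(paths))
  }
  if (inherits(x, "duplex")) x <- list(x)
  write_pdb_frames(x, path)
  invisible(path)
}

#' @noRd
write_pdb_frames <- function(frames, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(frames)) {
    rows <- pdb_rows(frames[[f]])
    writeLines(sprintf("MODEL     %4d", f), con)
    name_fmt <- ifelse(nchar(rows$atom) < 4,
                       sprintf(" %-3s", rows$atom),
                       rows$atom)
    lines <- sprintf(
      "ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(rows)), name_fmt, paste0("D", rows$base), rows$chain,
      rows$resseq, rows$x, rows$y, rows$z, 1.0, 0.0, rows$element)
    writeLines(lines, con)
    writeLines(c("TER", "ENDMDL"), con)
  }
  writeLines("END", con)
}

#' Read a multi-model PDB ensemble
#'
#' Parses one file per run; every MODEL becomes a frame.  The topology
#' (chains, residues, atom names) must be identical across models; drift
#' is reported with the first offending model.
#'
#' @param paths Character vector of PDB files, one per run.
#' @param burn_in_frames Leading frames to flag as burn-in (default 0).
#' @return A `trajectory_ensemble` (without ground truth).
#' @export
read_ensemble <- function(paths, burn_in_frames = 0) {
  runs <- vector("list", length(paths))
  topo <- NULL
  key0 <- NULL
  for (p in seq_along(paths)) {
    lines <- readLines(paths[p])
    if (!length(lines)) stop("empty file: ", paths[p])
    model_starts <- grep("^MODEL", lines)
    if (!length(model_starts)) stop("no MODEL records in ", paths[p])
    atom_idx <- grep("^ATOM", lines)
    model_of <- findInterval(atom_idx, model_starts)
    atoms <- data.frame(
      model = model_of,
      atom = trimws(substr(lines[atom_idx], 13, 16)),
      resname = trimws(substr(lines[atom_idx], 18, 20)),
      chain = substr(lines[atom_idx], 22, 22),
      resseq = as.integer(substr(lines[atom_idx], 23, 26)),
      x = as.numeric(substr(lines[atom_idx], 31, 38)),
      y = as.numeric(substr(lines[atom_idx], 39, 46)),
      z = as.numeric(substr(lines[atom_idx], 47, 54)),
      stringsAsFactors = FALSE)
    n_models <- max(atoms$model)
    first <- atoms[atoms$model == 1, , drop = FALSE]
    key <- paste(first$atom, first$resname, first$chain, first$resseq)
    for (mdl in seq_len(n_models)) {
      m <- atoms[atoms$model == mdl, , drop = FALSE]
      if (nrow(m) != nrow(first) ||
          !identical(paste(m$atom, m$resname, m$chain, m$resseq), key)) {
        stop("topology drift in ", paths[p], " at MODEL ", mdl)
      }
    }
    if (is.null(topo)) {
      key0 <- key
      n <- max(first$resseq[first$chain == "A"])
      seq_i <- character(n); seq_ii <- character(n)
      for (i in seq_len(n)) {
        seq_i[i] <- sub("^D", "", first$resname[first$chain == "A" &
                                                  first$resseq == i][1])
        seq_ii[i] <- sub("^D", "", first$resname[first$chain == "B" &
                                                   first$resseq == n + 1 - i][1])
      }
      topo <- build_duplex(seq_i, seq_ii)
      # atom order mapping from file order to topology order
      pair <- ifelse(first$chain == "A", first$resseq, n + 1 - first$resseq)
      strand <- ifelse(first$chain == "A", "I", "II")
      map <- match(paste(topo$atoms$strand, topo$atoms$pair, topo$atoms$atom),
                   paste(strand, pair, first$atom))
      if (anyNA(map)) stop("atoms in ", paths[p],
                           " do not match the expected topology")
    } else if (!identical(key, key0)) {
      stop("topology drift between ", paths[1], " and ", paths[p])
    }
    coords <- array(NA_real_, c(nrow(topo$atoms), 3, n_models))
    for (mdl in seq_len(n_models)) {
      m <- atoms[atoms$model == mdl, , drop = FALSE]
      coords[, , mdl] <- as.matrix(m[map, c("x", "y", "z")])
    }
    runs[[p]] <- coords
  }
  structure(list(topology = topo, runs = runs, ground_truth = NULL,
                 burn_in = burn_in_frames, config = NULL),
            class = "trajectory_ensemble")
}

#' Write the generator ground truth as TSV
#'
#' Long table: `run`, `frame`, `kind` (pair/step), `index`, `parameter`,
#' `value`, `hidden_state` (open/closed label where a two-state process
#' was active, else NA).
#'
#' @param ensemble A `trajectory_ensemble` from [generate_trajectory()].
#' @param path Output file.
#' @export
write_ground_truth <- function(ensemble, path) {
  if (is.null(ensemble$ground_truth)) stop("ensemble carries no ground truth")
  rows <- list()
  for (r in seq_along(ensemble$ground_truth)) {
    gt <- ensemble$ground_truth[[r]]
    nf <- dim(gt$pair)[3]
    n <- dim(gt$pair)[1]
    for (f in seq_len(nf)) {
      rows[[length(rows) + 1]] <- data.frame(
        run = r, frame = f,
        kind = c(rep("pair", n * 6), rep("step", (n - 1) * 6)),
        index = c(rep(seq_len(n), 6), rep(seq_len(n - 1), 6)),
        parameter = c(rep(PAIR_PARAMS, each = n),
                      rep(STEP_PARAMS, each = n - 1)),
        value = c(as.vector(gt$pair[, , f]), as.vector(gt$step[, , f])),
        hidden_state = gt$labels[f])
    }
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
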