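# Cooperative-site caller: dinucleotide-preserving decoys, FDR curves
# and the rank-comparison rule between cooperative and single-protein
# model sets.

#' Dinucleotide-preserving sequence shuffle
#'
#' Permutes each sequence while preserving all dinucleotide counts and
#' the first and last base, using the Eulerian-walk construction of
#' Altschul and Erickson: the transition multigraph of the sequence is
#' rewired by drawing a random last-edge arborescence into the terminal
#' base and permuting the remaining out-edges uniformly. `N`s (or any
#' other letter) are treated as an additional symbol, so their counts
#' are preserved too.
#'
#' @param sequences Character vector.
#' @param seed Integer seed (`NULL` uses the current RNG stream).
#' @return Character vector of shuffled sequences.
#' @export
#' @examples
#' dinucleotide_shuffle("CCGGAAGTGACGTCAC", seed = 1)
dinucleotide_shuffle <- function(sequences, seed = NULL) {
  if (any(nchar(sequences) < 2)) abort("sequences must have length >= 2")
  with_seed_or_not(seed, vapply(sequences, shuffle_one, character(1),
                                USE.NAMES = FALSE))
}

shuffle_one <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  verts <- unique(chars)
  if (length(verts) == 1L) return(s)
  from <- chars[-n]
  to <- chars[-1L]
  f <- chars[n]
  # out-edge target lists per vertex
  adj <- split(to, factor(from, levels = verts))
  # draw last-edge choices until they form an arborescence into f
  nonfinal <- setdiff(names(adj)[lengths(adj) > 0L], f)
  vi <- seq_along(verts); names(vi) <- verts
  for (attempt in 1:10000) {
    last <- vapply(adj[nonfinal], function(t) t[sample.int(length(t), 1L)],
                   character(1))
    ok <- TRUE
    for (v in nonfinal) {
      cur <- v
      for (step in seq_along(verts)) {
        if (cur == f) break
        cur <- unname(last[cur])
        if (is.na(cur)) break  # dead end (vertex with no out-edges != f)
      }
      if (!identical(cur, f)) { ok <- FALSE; break }
    }
    if (ok) break
    if (attempt == 10000) abort("dinucleotide shuffle failed to converge")
  }
  # order out-edges: random permutation, designated last edge at the end
  ordered <- lapply(names(adj), function(v) {
    t <- adj[[v]]
    if (length(t) == 0L) return(t)
    if (v %in% names(last)) {
      li <- which(t == last[[v]])[1]
      rest <- t[-li]
      c(rest[sample.int(length(rest))], t[li])
    } else {
      t[sample.int(length(t))]
    }
  })
  names(ordered) <- names(adj)
  # Eulerian walk from the first base
  ptr <- setNames(rep(1L, length(adj)), names(adj))
  out <- character(n)
  out[1] <- chars[1]
  cur <- chars[1]
  for (i in 2:n) {
    nxt <- ordered[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}

#' False discovery rate curve from real and scrambled scores
#'
#' Pools the real and decoy score lists and evaluates, at every distinct
#' score cutoff, the number of real and scrambled scores at or above the
#' cutoff and the FDR — the fraction of at-or-above-cutoff sequences
#' that are scrambled. Ties are counted on the at-or-above side for both
#' lists.
#'
#' @param real,scrambled Numeric score vectors.
#' @return Tibble of class `fdr_curve`, ascending in `cutoff`:
#'   `n_real_ge`, `n_scrambled_ge`, `fdr`.
#' @export
fdr_curve <- function(real, scrambled) {
  if (length(real) == 0 || length(scrambled) == 0) {
    abort("both score lists must be nonempty")
  }
  cutoffs <- sort(unique(c(real, scrambled)))
  sr <- sort(real)
  ss <- sort(scrambled)
  n_real_ge <- length(sr) - findInterval(cutoffs, sr, left.open = TRUE)
  n_scr_ge <- length(ss) - findInterval(cutoffs, ss, left.open = TRUE)
  out <- tibble(cutoff = cutoffs, n_real_ge = n_real_ge,
                n_scrambled_ge = n_scr_ge,
                fdr = n_scr_ge / (n_real_ge + n_scr_ge))
  structure(out, class = c("fdr_curve", class(tibble())))
}

#' @rdname fdr_curve
#' @param curve An `fdr_curve`.
#' @param scores Scores at which to evaluate the FDR (the FDR at the
#'   smallest curve cutoff at or above each score; 0 above the largest
#'   cutoff, where nothing remains).
#' @export
fdr_at <- function(curve, scores) {
  idx <- findInterval(scores, curve$cutoff, left.open = TRUE) + 1L
  out <- rep(0, length(scores))
  ok <- idx <= nrow(curve)
  out[ok] <- curve$fdr[idx[ok]]
  out
}

#' Score and rank regions under a set of energy models
#'
#' Scores every region with every model ([energy_score()]) and assigns
#' competition ranks per model (rank 1 = best score; ties share the
#' minimal rank). Regions shorter than a model are scored missing for
#' that model.
#'
#' @param models Named list of `energy_model`s.
#' @param sequences Named character vector of region sequences.
#' @param both_strands Scan both strands.
#' @return Tibble `region`, `model`, `score`, `rank`.
#' @export
rank_regions <- function(models, sequences, both_strands = TRUE) {
  if (length(models) == 0 || length(sequences) == 0) {
    abort("need at least one model and one region")
  }
  if (is.null(names(models))) names(models) <- paste0("model", seq_along(models))
  purrr::imap_dfr(models, function(m, nm) {
    sc <- energy_score(m, sequences, both_strands = both_strands)
    tibble(region = sc$id, model = nm, score = sc$best_score,
           rank = dplyr::min_rank(dplyr::desc(sc$best_score)))
  })
}

#' @rdname rank_regions
#' @param ranked Output of `rank_regions()`.
#' @return `best_over_models()`: per-region best (maximal) score and
#'   best (minimal) rank over the model set.
#' @export
best_over_models <- function(ranked) {
  ranked %>%
    group_by(.data$region) %>%
    summarise(best_score = max(.data$score, na.rm = TRUE),
              best_rank = min(.data$rank, na.rm = TRUE), .groups = "drop")
}

#' Call regions cooperatively bound by GABPa and CREB1
#'
#' Builds one dinucleotide-preserving decoy per region, scores real and
#' decoy sequences under every model of the cooperative
#' (GABPa+CREB1-derived) and single-protein model sets with the same
#' best-window reduction, estimates each region's FDR per model from the
#' pooled real/decoy list ([fdr_curve()]), and applies the calling rule:
#' a region is cooperative iff its FDR is below `fdr_coop` under at
#' least one cooperative model and at or above `fdr_single` under every
#' single-protein model.
#'
#' @param sequences Named character vector of region sequences (e.g.
#'   extracted from co-bound ChIP peaks).
#' @param coop_models,single_models Named lists of `energy_model`s.
#' @param fdr_coop Cooperative-set FDR threshold (default 5%).
#' @param fdr_single Single-set FDR floor (default 15%).
#' @param seed Integer seed for decoy construction.
#' @param both_strands Scan both strands.
#' @return Tibble of class `coop_calls`: per region the best score and
#'   competition rank under each model set, the minimal FDR per set and
#'   the call flag; decoy scores are attached as attribute
#'   `"decoy_scores"` for plotting.
#' @export
call_cooperative <- function(sequences, coop_models, single_models,
                             fdr_coop = 0.05, fdr_single = 0.15,
                             seed = 1L, both_strands = TRUE) {
  if (fdr_coop < 0 || fdr_coop > 1 || fdr_single < 0 || fdr_single > 1) {
    abort("FDR thresholds must lie in [0, 1]")
  }
  if (length(coop_models) == 0 || length(single_models) == 0) {
    abort("both model sets must be nonempty")
  }
  if (is.null(names(sequences))) {
    names(sequences) <- paste0("region", seq_along(sequences))
  }
  decoys <- dinucleotide_shuffle(sequences, seed = seed)
  names(decoys) <- paste0(names(sequences), "_shuf")
  side <- function(models, label) {
    per_model <- purrr::imap(models, function(m, nm) {
      real_sc <- energy_score(m, sequences, both_strands = both_strands)
      dec_sc <- energy_score(m, decoys, both_strands = both_strands)
      curve <- fdr_curve(real_sc$best_score, dec_sc$best_score)
      tibble(region = real_sc$id, model = nm, score = real_sc$best_score,
             rank = dplyr::min_rank(dplyr::desc(real_sc$best_score)),
             fdr = fdr_at(curve, real_sc$best_score))
    })
    dplyr::bind_rows(per_model) %>%
      group_by(.data$region) %>%
      summarise("best_{label}_score" := max(.data$score),
                "best_{label}_rank" := min(.data$rank),
                "fdr_{label}" := min(.data$fdr), .groups = "drop")
  }
  coop <- side(coop_models, "coop")
  single <- side(single_models, "single")
  decoy_best <- function(models) {
    purrr::map(models, function(m) {
      energy_score(m, decoys, both_strands = both_strands)$best_score
    }) %>% purrr::reduce(pmax)
  }
  out <- inner_join(coop, single, by = "region") %>%
    mutate(is_cooperative = .data$fdr_coop < !!fdr_coop &
             .data$fdr_single >= !!fdr_single) %>%
    arrange(match(.data$region, names(sequences)))
  attr(out, "decoy_scores") <- tibble(
    region = names(decoys),
    best_coop_score = decoy_best(coop_models),
    best_single_score = decoy_best(single_models)
  )
  attr(out, "thresholds") <- c(fdr_coop = fdr_coop, fdr_single = fdr_single)
  structure(out, class = c("coop_calls", class(tibble())))
}
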