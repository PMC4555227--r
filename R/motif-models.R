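# Energy models: PWMs built from SNP-panel medians, PFM conversion,
# BEEML-style occupancy scoring, and plain-text matrix IO.

#' Construct an energy model from a PWM
#'
#' An energy model couples a position weight matrix (per-position
#' relative weights in (0,1], maximum 1 per column) with the position
#' frequency matrix obtained by renormalising each column to sum 1, and
#' the scoring parameters of a BEEML-style occupancy transform: a window
#' of sequence is assigned the energy `E = sum_i eps_i(b_i)` with
#' `eps_i(b) = -log(f_i(b) + pseudo) + log(max_b f_i(b) + pseudo)`, and
#' the score `1 / (1 + exp(E - mu))`. The consensus window therefore has
#' `E = 0` and score `1/(1 + exp(-mu))` (0.5 at the default `mu = 0`);
#' ranks are invariant to `mu`.
#'
#' @param pwm Numeric 4 x L matrix, rows named `A,C,G,T`, values in
#'   (0,1] with column maxima 1.
#' @param mu Chemical-potential offset of the occupancy transform.
#' @param pseudo Pseudo-frequency keeping energies finite.
#' @param name Optional model name.
#' @return An object of class `energy_model` with elements `pwm`, `pfm`,
#'   `mu`, `pseudo`, `name`.
#' @export
energy_model <- function(pwm, mu = 0, pseudo = 1e-3, name = NULL) {
  pwm <- as.matrix(pwm)
  if (!identical(rownames(pwm), BASES)) {
    if (nrow(pwm) != 4) abort("pwm must have 4 rows (A, C, G, T)")
    rownames(pwm) <- BASES
  }
  if (any(pwm <= 0) || any(pwm > 1)) abort("pwm weights must lie in (0, 1]")
  if (any(abs(apply(pwm, 2, max) - 1) > 1e-9)) {
    abort("each pwm column must have maximum weight 1")
  }
  pfm <- sweep(pwm, 2, colSums(pwm), "/")
  structure(list(pwm = pwm, pfm = pfm, mu = mu, pseudo = pseudo,
                 name = name %||% "energy_model"),
            class = "energy_model")
}

#' @export
print.energy_model <- function(x, ...) {
  cat(sprintf("<energy_model '%s'> L = %d, mu = %g, pseudo = %g\n",
              x$name, ncol(x$pwm), x$mu, x$pseudo))
  cat("PWM:\n")
  print(round(x$pwm, 3))
  invisible(x)
}

#' @export
length.energy_model <- function(x) ncol(x$pwm)

# mismatch energies eps_i(b), 4 x L
model_energies <- function(model) {
  f <- model$pfm + model$pseudo
  sweep(-log(f), 2, -log(apply(f, 2, max)), "-")
}

#' Build a PWM from SNP-panel median intensities
#'
#' Implements the array-derived binding model: the panel sequence with
#' the highest median intensity across its replicate probes is `S_max`;
#' every other variant receives the relative score
#' `r = median / median(S_max)`. Column `i` of the PWM assigns weight 1
#' to the base `S_max` carries at position `i` and the relative score of
#' the corresponding single-base variant to each other base. When
#' `S_max` is not the canonical consensus (as in the weak-motif panel,
#' where the position-1 variant restores the strong motif), relative
#' scores are still taken against `S_max`. Relative scores are floored
#' at `pseudo` so that mismatch energies stay finite.
#'
#' @param panel Panel summary from [summarize_snp_panel()].
#' @param mu,pseudo,name Passed to [energy_model()].
#' @return An `energy_model`.
#' @export
build_pwm_from_panel <- function(panel, mu = 0, pseudo = 1e-3, name = NULL) {
  if (any(is.na(panel$median))) {
    missing <- panel$seq[is.na(panel$median)]
    abort(paste("panel medians missing for:",
                paste(head(missing, 5), collapse = ", ")))
  }
  cons <- panel$seq[panel$role == "consensus"]
  L <- nchar(cons)
  smax <- s_max(panel)
  med <- setNames(panel$median, panel$seq)
  cons_chars <- strsplit(cons, "")[[1]]
  pwm <- matrix(NA_real_, 4, L, dimnames = list(BASES, NULL))
  for (i in seq_len(L)) {
    col_med <- vapply(BASES, function(b) {
      v <- cons_chars; v[i] <- b
      cand <- paste(v, collapse = "")
      if (is.na(med[cand])) {
        abort(sprintf("panel is missing variant %s (pos %d, %s)", cand, i, b))
      }
      unname(med[cand])
    }, numeric(1))
    pwm[, i] <- col_med / smax$median
    # the per-position highest-median base carries weight 1
    pwm[which.max(col_med), i] <- 1
  }
  pwm <- pmin(pmax(pwm, pseudo), 1)
  energy_model(pwm, mu = mu, pseudo = pseudo, name = name)
}

#' Renormalise a model's position frequency matrix
#'
#' Converts the PWM to a PFM by dividing each column by its sum; columns
#' of the result sum to 1. Applied automatically by [energy_model()];
#' exposed for idempotence and for models read from matrix files.
#'
#' @param model An `energy_model`.
#' @return The model with a freshly normalised `pfm`.
#' @export
pwm_to_pfm <- function(model) {
  stopifnot(inherits(model, "energy_model"))
  model$pfm <- sweep(model$pwm, 2, colSums(model$pwm), "/")
  model
}

#' Score sequences with an energy model
#'
#' Slides the model over every window of each sequence (both strands by
#' default), computes the BEEML-style occupancy score of each window and
#' reports the best window per sequence. Windows containing ambiguous
#' bases are skipped; a sequence with no scorable window gets score 0.
#'
#' @param model An `energy_model`.
#' @param sequences Named character vector (or unnamed; ids are made up).
#' @param both_strands Also scan the reverse complement.
#' @return Tibble `id`, `best_score`, `offset` (1-based, forward
#'   coordinates), `strand`.
#' @export
energy_score <- function(model, sequences, both_strands = TRUE) {
  stopifnot(inherits(model, "energy_model"))
  ids <- names(sequences) %||% paste0("seq", seq_along(sequences))
  ids[!nzchar(ids)] <- paste0("seq", which(!nzchar(ids)))
  eps <- model_energies(model)
  L <- ncol(eps)
  skipped <- 0L
  rows <- purrr::map2_dfr(sequences, ids, function(s, id) {
    n <- nchar(s)
    if (n < L) {
      return(tibble(id = id, best_score = NA_real_, offset = NA_integer_,
                    strand = NA_character_))
    }
    score_one <- function(str) {
      codes <- match(strsplit(str, "")[[1]], BASES)
      W <- n - L + 1L
      idx <- outer(seq_len(L) - 1L, seq_len(W), "+")  # L x W of positions
      ev <- matrix(eps[cbind(codes[idx], rep(seq_len(L), W))], nrow = L)
      colSums(ev)  # NA where a window holds an ambiguous base
    }
    e_fwd <- score_one(s)
    e <- e_fwd
    strands <- rep("+", length(e_fwd))
    offsets <- seq_along(e_fwd)
    if (both_strands) {
      e_rev <- score_one(revcomp(s))
      # window w on the reverse strand starts at forward offset n-L+2-w... i.e.
      offs_rev <- rev(seq_along(e_rev))
      e <- c(e, e_rev)
      strands <- c(strands, rep("-", length(e_rev)))
      offsets <- c(offsets, offs_rev)
    }
    ok <- !is.na(e)
    if (!any(ok)) {
      skipped <<- skipped + 1L
      return(tibble(id = id, best_score = 0, offset = NA_integer_,
                    strand = NA_character_))
    }
    best <- which(ok)[which.min(e[ok])]
    tibble(id = id, best_score = 1 / (1 + exp(e[best] - model$mu)),
           offset = offsets[best], strand = strands[best])
  })
  if (skipped > 0) {
    warn(sprintf("%d sequence(s) had no scorable window; scored 0", skipped))
  }
  if (any(is.na(rows$best_score))) {
    warn(sprintf("%d sequence(s) shorter than the model; scored missing",
                 sum(is.na(rows$best_score))))
  }
  rows
}

#' Write or read an energy model as a plain-text matrix file
#'
#' The file is JASPAR-like: a header line `>name mu=<mu> pseudo=<pseudo>`
#' followed by four rows `A [ w1 w2 ... ]` (row-major, weights with full
#' precision). `read_motif_matrix()` also accepts column-major layouts
#' (a header row naming `A C G T` followed by one line per position) and
#' bare 4-row matrices without brackets; matrices whose columns sum to 1
#' are interpreted as PFMs and converted to weights, anything else as a
#' PWM (renormalised to column maximum 1). Negative entries are an
#' error.
#'
#' @param model An `energy_model`.
#' @param path File path.
#' @param mu,pseudo,name Overrides for files lacking header metadata.
#' @return `write_motif_matrix()`: the path, invisibly;
#'   `read_motif_matrix()`: an `energy_model`.
#' @export
write_motif_matrix <- function(model, path) {
  stopifnot(inherits(model, "energy_model"))
  lines <- c(
    sprintf(">%s mu=%s pseudo=%s", model$name,
            format(model$mu, digits = 17), format(model$pseudo, digits = 17)),
    vapply(BASES, function(b) {
      sprintf("%s [ %s ]", b,
              paste(format(model$pwm[b, ], digits = 17), collapse = " "))
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_motif_matrix
#' @export
read_motif_matrix <- function(path, mu = 0, pseudo = 1e-3, name = NULL) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (startsWith(lines[1], ">")) {
    hdr <- sub("^>", "", lines[1])
    name <- name %||% strsplit(hdr, "\\s+")[[1]][1]
    mu_m <- regmatches(hdr, regexpr("mu=[-0-9.eE+]+", hdr))
    if (length(mu_m)) mu <- as.numeric(sub("mu=", "", mu_m))
    ps_m <- regmatches(hdr, regexpr("pseudo=[-0-9.eE+]+", hdr))
    if (length(ps_m)) pseudo <- as.numeric(sub("pseudo=", "", ps_m))
    lines <- lines[-1]
  }
  parse_row <- function(l) {
    as.numeric(strsplit(trimws(gsub("[][|]", " ", l)), "\\s+")[[1]])
  }
  toks1 <- toupper(strsplit(trimws(lines[1]), "\\s+")[[1]])
  header_row <- all(toks1 %in% c(BASES, "POS", "POSITION", "#"))
  first_tok <- toupper(sub("[^A-Za-z0-9].*", "", lines[1]))
  mat <- if (!header_row && first_tok %in% BASES && length(lines) >= 4) {
    # row-major: lines start with the base letter
    rows <- lapply(lines[1:4], function(l) {
      base <- toupper(sub("[^A-Za-z].*", "", l))
      list(base = base, vals = parse_row(sub("^[A-Za-z]+[:]?", "", l)))
    })
    m <- do.call(rbind, lapply(rows, `[[`, "vals"))
    rownames(m) <- vapply(rows, `[[`, character(1), "base")
    m[BASES, , drop = FALSE]
  } else {
    # column-major: header naming the bases, one line per position
    hdr <- toupper(strsplit(lines[1], "\\s+")[[1]])
    base_cols <- match(BASES, hdr)
    if (any(is.na(base_cols))) abort("cannot determine matrix layout")
    vals <- do.call(rbind, lapply(lines[-1], parse_row))
    t(vals[, base_cols, drop = FALSE])
  }
  if (any(is.na(mat))) abort("malformed matrix file")
  if (any(mat < 0)) abort("matrix contains negative values")
  colsums <- colSums(mat)
  if (any(colsums == 0)) abort("matrix contains an all-zero column")
  # weights: column maxima 1 (this both accepts PWMs as written and
  # converts count/frequency matrices, whose columns share one scale)
  mat <- sweep(mat, 2, apply(mat, 2, max), "/")
  mat <- pmin(pmax(mat, pseudo), 1)
  rownames(mat) <- BASES
  energy_model(mat, mu = mu, pseudo = pseudo,
               name = name %||% "energy_model")
}
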