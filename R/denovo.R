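# De novo sequencing: theoretical b/y series, ladder interpretation of
# MS/MS spectra, overlap assembly of digest fragments, and enzymatic
# resolution of the isobaric Lys/Gln and Leu/Ile pairs.
#
# Conventions: singly charged ions (MALDI); fixed carbamidomethylation of
# Cys (a 160.0307 Da pseudo-residue); ambiguity codes in output sequences:
# 'J' for Leu/Ile; Lys/Gln ambiguity is kept as the nearest-mass base
# letter with a per-position flag (no letter is borrowed from the B/Z
# conventions, which mean other pairs).

.MASS_CAM_CYS <- 103.00919 + 57.0214637  # 160.03065

#' Theoretical b- and y-ion series
#'
#' Singly charged N-terminal b-ions and C-terminal y-ions of a peptide:
#' `b_i` is the first `i` residues (plus modifications) plus a proton;
#' `y_j` the last `j` residues plus water and a proton. Complementary pairs
#' satisfy `b_i + y_(n-i) = M + 2 * 1.00728`.
#'
#' @param x a `crp_peptide` or character sequence.
#' @param ... passed to [peptide()] for character input (e.g. `cam = TRUE`).
#' @return list with numeric vectors `b` and `y` (lengths `n - 1`).
#' @examples
#' ion_series("AG")
#' @export
ion_series <- function(x, ...) {
  p <- .as_peptide(x, ...)
  chars <- .seq_chars(p$sequence)
  n <- length(chars)
  if (n < 2) stop("ion series need at least 2 residues")
  res <- unname(.AA_MONO[chars])
  if (!is.null(p$modifications) && nrow(p$modifications)) {
    for (i in seq_len(nrow(p$modifications))) {
      pos <- p$modifications$position[i]
      res[pos] <- res[pos] + p$modifications$delta_mass[i]
    }
  }
  pre <- cumsum(res)
  list(b = pre[-n] + .MASS_PROTON,
       y = cumsum(rev(res))[-n] + .MASS_H2O + .MASS_PROTON)
}

#' Construct an MS/MS spectrum
#'
#' @param precursor_mh singly protonated precursor mass (Da).
#' @param mz fragment m/z values.
#' @param intensity fragment intensities (default 1).
#' @return object of class `msms_spectrum`.
#' @export
msms_spectrum <- function(precursor_mh, mz, intensity = NULL) {
  if (is.null(intensity)) intensity <- rep(1, length(mz))
  peaks <- .as_peaklist(data.frame(mz = mz, intensity = intensity))
  structure(list(precursor_mh = precursor_mh, peaks = peaks),
            class = "msms_spectrum")
}

#' @export
print.msms_spectrum <- function(x, ...) {
  cat(sprintf("msms_spectrum: precursor [M+H]+ %.4f, %d peaks\n",
              x$precursor_mh, nrow(x$peaks)))
  invisible(x)
}

# Residue gap table used for ladder chaining. L/I are collapsed to the 'J'
# ambiguity code; Cys appears as its carbamidomethylated mass in cam mode.
.gap_table <- function(cam = TRUE) {
  m <- .AA_MONO[setdiff(.AA_CODES, "I")]
  if (cam) m[["C"]] <- .MASS_CAM_CYS
  data.frame(letter = ifelse(names(m) == "L", "J", names(m)),
             mass = unname(m))
}

# Options for a single-residue gap d: letters within tol, with the K/Q pair
# compressed to the nearest-mass base letter plus a kq flag.
.gap_options <- function(d, gaps, tol) {
  hit <- which(abs(d - gaps$mass) <= tol)
  if (!length(hit)) return(NULL)
  letters <- gaps$letter[hit]
  resid <- abs(d - gaps$mass[hit])
  kq <- c("K", "Q")
  if (all(kq %in% letters)) {
    best_kq <- kq[which.min(c(resid[letters == "K"], resid[letters == "Q"]))]
    keep <- !(letters %in% setdiff(kq, best_kq))
    letters <- letters[keep]; resid <- resid[keep]
    flags <- letters == best_kq
  } else flags <- rep(FALSE, length(letters))
  ord <- order(resid)
  lapply(ord, function(i)
    list(letters = letters[i], kq = flags[i], residual = resid[i]))
}

# Options for a dipeptide bridge over gap d (one missing ladder position).
.bridge_options <- function(d, gaps, tol, max_options = 8) {
  n <- nrow(gaps)
  sums <- outer(gaps$mass, gaps$mass, "+")
  hit <- which(abs(d - sums) <= tol, arr.ind = TRUE)
  if (!nrow(hit)) return(NULL)
  opts <- lapply(seq_len(nrow(hit)), function(r) {
    i <- hit[r, 1]; j <- hit[r, 2]
    list(letters = c(gaps$letter[i], gaps$letter[j]),
         kq = c(FALSE, FALSE),
         residual = abs(d - sums[i, j]))
  })
  # collapse K/Q variants that differ below the tolerance to a flagged base
  key <- vapply(opts, function(o)
    paste(gsub("Q", "K", o$letters), collapse = ""), character(1))
  out <- list()
  for (k in unique(key)) {
    grp <- opts[key == k]
    best <- grp[[order(vapply(grp, `[[`, numeric(1), "residual"))[1]]]
    if (length(grp) > 1)
      best$kq <- best$letters %in% c("K", "Q")
    out[[length(out) + 1L]] <- best
  }
  out <- out[order(vapply(out, `[[`, numeric(1), "residual"))]
  utils::head(out, max_options)
}

#' Interpret an MS/MS spectrum into sequence candidates
#'
#' Chains fragment peaks whose mass gaps match residue masses into b-/y-ion
#' ladders, merging the two series through the complementarity identity
#' (every peak is considered both as a b-ion and as the complement of a
#' y-ion). A single missing ladder position may be bridged by a dipeptide
#' gap. Candidates are ranked by ion coverage, then summed supporting
#' intensity, then lexicographically. Leu/Ile is always reported as the
#' ambiguity code `J`; Lys/Gln is flagged ambiguous whenever `tol` cannot
#' separate the 0.0364 Da pair (i.e. for all realistic MALDI-TOF/TOF
#' tolerances) and is resolved later by [resolve_isobaric()].
#'
#' @param spectrum an [msms_spectrum()].
#' @param tol fragment tolerance in Da (default 0.05).
#' @param cam treat cysteines as carbamidomethylated.
#' @param allow_bridge permit one-position dipeptide bridges.
#' @param max_candidates maximum candidates returned.
#' @param beam partial ladders kept per spectrum node during the dynamic
#'   program (default 50, or `max_candidates` if larger).
#' @param penalty_scale,penalty_deadband mass-accuracy penalty shape: each
#'   edge costs `((residual - deadband)_+ / scale)^2` support points, so
#'   residuals within the deadband (calibration jitter) are free while
#'   matches near the tolerance edge are expensive.
#' @return list of `seq_candidate` objects, each with elements `sequence`,
#'   `coverage`, `flags` (per-position data.frame), `mass_residual`.
#' @export
interpret_spectrum <- function(spectrum, tol = 0.05, cam = TRUE,
                               allow_bridge = TRUE, max_candidates = 20,
                               beam = NULL, penalty_scale = tol / 5,
                               penalty_deadband = 0.3 * tol) {
  stopifnot(inherits(spectrum, "msms_spectrum"))
  if (tol <= 0) stop("tol must be positive")
  peaks <- spectrum$peaks
  if (!nrow(peaks)) return(list())
  MH <- spectrum$precursor_mh
  start_m <- .MASS_PROTON
  end_m <- MH - .MASS_H2O          # virtual b_n
  gaps <- .gap_table(cam)
  min_gap <- min(gaps$mass) - tol

  # prefix-space nodes: each peak as a b-ion, and as the b-complement of a
  # y-ion (b_i = MH + proton - y_(n-i))
  cand <- rbind(
    data.frame(m = peaks$mz, inten = peaks$intensity),
    data.frame(m = MH + .MASS_PROTON - peaks$mz, inten = peaks$intensity))
  cand <- cand[cand$m > start_m + min_gap & cand$m < end_m - min_gap, ,
               drop = FALSE]
  cand <- cand[order(cand$m), , drop = FALSE]
  # merge nodes closer than tol/2
  nodes <- list()
  for (i in seq_len(nrow(cand))) {
    last <- if (length(nodes)) nodes[[length(nodes)]] else NULL
    if (!is.null(last) && cand$m[i] - last$m <= tol / 2) {
      last$m <- (last$m * last$k + cand$m[i]) / (last$k + 1)
      last$inten <- last$inten + cand$inten[i]
      last$k <- last$k + 1
      nodes[[length(nodes)]] <- last
    } else {
      nodes[[length(nodes) + 1L]] <- list(m = cand$m[i],
                                          inten = cand$inten[i], k = 1)
    }
  }
  node_m <- c(start_m, vapply(nodes, `[[`, numeric(1), "m"), end_m)
  node_i <- c(0, vapply(nodes, `[[`, numeric(1), "inten"), 0)
  nn <- length(node_m)
  start_id <- 1L; end_id <- nn
  # complement partner of each internal node: the same peaks read in the
  # other ion series (b_i and y_(n-i) sum to MH + proton). A physical
  # ladder consumes each peak in one role only, so a path may not visit
  # both a node and its complement -- this bars "hybrid" readings that
  # double-count the two series as separate positions.
  partner <- rep(NA_integer_, nn)
  for (i in 2:(nn - 1L)) {
    tgt <- MH + .MASS_PROTON - node_m[i]
    j <- which(abs(node_m - tgt) <= tol / 2)
    j <- setdiff(j, c(start_id, end_id, i))
    if (length(j)) partner[i] <- j[which.min(abs(node_m[j] - tgt))]
  }

  # adjacency: single-residue edges, then bridges where no supported
  # two-step path exists
  adj <- vector("list", nn)
  single <- matrix(FALSE, nn, nn)
  for (i in seq_len(nn - 1L)) {
    edges <- list()
    for (j in (i + 1L):nn) {
      d <- node_m[j] - node_m[i]
      if (d > 2 * max(gaps$mass) + tol) break
      opts <- .gap_options(d, gaps, tol)
      if (!is.null(opts)) {
        single[i, j] <- TRUE
        edges[[length(edges) + 1L]] <- list(to = j, opts = opts,
                                            bridge = FALSE)
      }
    }
    adj[[i]] <- edges
  }
  if (allow_bridge) {
    for (i in seq_len(nn - 1L)) {
      for (j in (i + 1L):nn) {
        d <- node_m[j] - node_m[i]
        # dipeptide sums start at 2x Gly and overlap the single-residue
        # range (e.g. Gly+Val vs Arg), so bridges can compete with singles
        if (d < 2 * min(gaps$mass) - tol) next
        if (d > 2 * max(gaps$mass) + tol) break
        # only repair gaps that no intermediate supported node explains
        if (any(single[i, ] & single[, j])) next
        opts <- .bridge_options(d, gaps, tol)
        if (is.null(opts)) next
        sing <- .gap_options(d, gaps, tol)
        if (!is.null(sing)) {
          # parsimony: inside the single-residue range a bridge is offered
          # only when it fits clearly better than the best single residue
          # (exact isobars like Gly+Gly vs Asn must read as one residue)
          best_single <- min(vapply(sing, `[[`, numeric(1), "residual"))
          opts <- Filter(function(o) o$residual < best_single - 0.005, opts)
          if (!length(opts)) next
        }
        adj[[i]][[length(adj[[i]]) + 1L]] <-
          list(to = j, opts = opts, bridge = TRUE)
      }
    }
  }

  # backward reachability to the end node
  reach <- logical(nn); reach[end_id] <- TRUE
  for (i in rev(seq_len(nn - 1L)))
    reach[i] <- any(vapply(adj[[i]], function(e) reach[e$to], logical(1)))
  if (!reach[start_id]) return(list())

  # beam dynamic programming over the reachable subgraph: at every node
  # keep the best partial ladders by (supported positions, intensity),
  # which bounds the otherwise exponential path enumeration while
  # retaining alternative interpretations (including the mirrored ladder)
  if (is.null(beam)) beam <- max(50L, max_candidates)
  # partial-ladder score: +1 per supported position, minus a quadratic
  # mass-accuracy penalty per edge, (residual / (tol/2))^2. Edges matching
  # at instrument accuracy cost almost nothing while coincidental matches
  # near the tolerance edge forfeit several support points -- this stops
  # dense "zig-zag" readings through mirror or decoy nodes from outranking
  # mass-consistent ladders without punishing honest calibration jitter.
  edge_penalty <- function(res) (max(0, res - penalty_deadband) / penalty_scale)^2
  # support balance: unsupported (inserted) positions count against a
  # reading, so a fully supported ladder outranks an insertion variant
  st_score <- function(s) sum(s$supported) - sum(!s$supported) - s$penalty
  empty_state <- list(letters = character(0), kq = logical(0),
                      supported = logical(0), residual = 0,
                      penalty = 0, inten = 0, visited = integer(0))
  prune <- function(st) {
    if (length(st) <= beam) return(st)
    ord <- order(-round(2 * vapply(st, st_score, numeric(1))) / 2,
                 vapply(st, function(s) sum(!s$supported), numeric(1)),
                 -vapply(st, `[[`, numeric(1), "inten"),
                 vapply(st, function(s) paste(s$letters, collapse = ""),
                        character(1)))
    st[ord[seq_len(beam)]]
  }
  run_dp <- function(use_exclusion) {
    states <- vector("list", nn)
    states[[start_id]] <- list(empty_state)
    for (i in seq_len(nn - 1L)) {
      if (!length(states[[i]]) || !reach[i]) next
      states[[i]] <- prune(states[[i]])
      for (e in adj[[i]]) {
        if (!reach[e$to]) next
        internal <- e$to != end_id
        excl <- if (use_exclusion && internal && !is.na(partner[e$to]))
          partner[e$to] else NA
        for (s in states[[i]]) {
          if (!is.na(excl) && excl %in% s$visited) next
          for (o in e$opts) {
            supp <- if (e$bridge) c(FALSE, internal) else internal
            states[[e$to]][[length(states[[e$to]]) + 1L]] <- list(
              letters = c(s$letters, o$letters),
              kq = c(s$kq, o$kq),
              supported = c(s$supported, supp),
              residual = s$residual + o$residual,
              penalty = s$penalty + edge_penalty(o$residual),
              inten = s$inten + if (internal) node_i[e$to] else 0,
              visited = if (internal) c(s$visited, e$to) else s$visited)
          }
        }
      }
      states[i] <- list(NULL)  # free, keeping list indices stable
    }
    states[[end_id]]
  }
  finals <- run_dp(use_exclusion = TRUE)
  # near mass-palindromic peptides legitimately pair a position with its
  # complement; if the exclusion leaves no complete ladder, run without it
  if (!length(finals)) finals <- run_dp(use_exclusion = FALSE)
  if (!length(finals)) return(list())

  cands <- list()
  for (s in finals) {
    nres <- length(s$letters)
    if (nres < 2) next
    # 'supported' marks each residue's right boundary; the last one is the
    # virtual b_n and does not count towards ladder coverage
    cov <- sum(s$supported[-nres]) / (nres - 1)
    seq_str <- paste(s$letters, collapse = "")
    base <- chartr("J", "L", seq_str)
    mres <- peptide_mass(peptide(base, cam = cam))[["MH"]] - MH
    cands[[length(cands) + 1L]] <- structure(list(
      sequence = seq_str,
      coverage = cov,
      score = st_score(s),
      sum_intensity = s$inten,
      mass_residual = mres,
      gap_residual = s$residual,
      flags = data.frame(position = seq_len(nres), letter = s$letters,
                         kq = s$kq, ji = s$letters == "J",
                         supported = c(s$supported[-nres], NA))),
      class = "seq_candidate")
  }
  if (!length(cands)) return(list())
  # ranked by the support-minus-penalty score, then summed supporting
  # intensity, then lexicographically; duplicates (same sequence and K/Q
  # flags) keep their best-scoring reading
  # scores are quantized to half-points for ranking: differences smaller
  # than that are jitter, and the parsimony keys below should decide
  ord <- order(-round(2 * vapply(cands, `[[`, numeric(1), "score")) / 2,
               -vapply(cands, `[[`, numeric(1), "coverage"),
               -vapply(cands, `[[`, numeric(1), "sum_intensity"),
               vapply(cands, `[[`, character(1), "sequence"))
  cands <- cands[ord]
  key <- vapply(cands, function(x)
    paste(x$sequence, paste(which(x$flags$kq), collapse = ","), sep = "|"),
    character(1))
  cands <- cands[!duplicated(key)]
  utils::head(cands, max_candidates)
}

#' @export
print.seq_candidate <- function(x, ...) {
  cat(sprintf("seq_candidate: %s (coverage %.2f, mass residual %+.3f Da%s)\n",
              x$sequence, x$coverage, x$mass_residual,
              if (any(x$flags$kq)) paste0(", K/Q ambiguous at ",
                paste(x$flags$position[x$flags$kq], collapse = ",")) else ""))
  invisible(x)
}

# ---- fragment assembly -----------------------------------------------------

# per-position letter sets: "J" -> L/I, kq-flagged -> K/Q
.letter_set <- function(letter, kq) {
  if (letter == "J") c("L", "I")
  else if (isTRUE(kq)) c("K", "Q")
  else letter
}

.set_to_letter <- function(set) {
  if (length(set) == 1L) list(letter = set, kq = FALSE, ji = FALSE)
  else if (setequal(set, c("L", "I"))) list(letter = "J", kq = FALSE, ji = TRUE)
  else if (setequal(set, c("K", "Q"))) list(letter = "K", kq = TRUE, ji = FALSE)
  else list(letter = set[1], kq = FALSE, ji = FALSE)
}

# isobar-aware composition agreement: J counts into the Leu/Ile pool and
# K/Q letters into a joint pool, everything else must match exactly
.composition_ok <- function(cons, composition) {
  chars <- strsplit(cons, "")[[1]]
  if (sum(chars %in% c("L", "I", "J")) !=
      composition[["L"]] + composition[["I"]]) return(FALSE)
  if (sum(chars %in% c("K", "Q")) !=
      composition[["K"]] + composition[["Q"]]) return(FALSE)
  for (r in setdiff(names(composition), c("L", "I", "K", "Q")))
    if (sum(chars == r) != composition[[r]]) return(FALSE)
  TRUE
}

.cand_sets <- function(cand) {
  chars <- .seq_chars(cand$sequence)
  kq <- cand$flags$kq
  list(sets = lapply(seq_along(chars),
                     function(i) .letter_set(chars[i], kq[i])),
       n = length(chars))
}

.norm_fragment <- function(f, max_alternatives) {
  alts <-
    if (!is.null(f$candidates)) {
      lapply(utils::head(f$candidates, max_alternatives), .cand_sets)
    } else if (inherits(f$candidate %||% NULL, "seq_candidate")) {
      list(.cand_sets(f$candidate))
    } else {
      chars <- .seq_chars(f$sequence)
      list(list(sets = lapply(chars, .letter_set, kq = FALSE),
                n = length(chars)))
    }
  list(alts = alts, enzyme = enzyme(f$enzyme))
}

#' Assemble digest fragments into a full-length sequence
#'
#' Orders overlapping (or abutting) fragment sequences from different
#' digests into a consensus, requiring agreement at every shared position
#' (ambiguity-aware: `J` matches Leu/Ile, a flagged Lys matches Lys/Gln)
#' and that each fragment's N-terminus either is the peptide N-terminus or
#' follows a cleavage residue of its own enzyme. Consensus candidates are
#' finally checked against the measured intact native mass, assuming all
#' cysteines pair into disulfides.
#'
#' @param fragments a data.frame with columns `sequence` and `enzyme`, or a
#'   list of lists each holding `enzyme` plus one of `sequence`,
#'   `candidate` (a `seq_candidate` from [interpret_spectrum()]) or
#'   `candidates` (the ranked candidate list itself, letting the assembler
#'   pick the interpretation -- in particular resolving the intrinsic
#'   forward/reverse ladder ambiguity through the overlap and boundary
#'   constraints).
#' @param intact_mh measured `[M+H]+` of the intact native peptide.
#' @param mass_tol tolerance for the intact mass check (Da). The default
#'   0.7 absorbs the calibration offset seen between linear-mode intact
#'   masses and reflector-mode fragment masses.
#' @param min_overlap minimum shared residues for two fragments to be
#'   considered overlapping (abutting placements are also allowed, and are
#'   reported as ambiguous when more than one ordering survives).
#' @param max_alternatives candidates considered per fragment when
#'   `candidates` lists are supplied.
#' @param max_states cap on placement states explored by the search.
#' @param composition optional measured residue counts (amino-acid
#'   analysis, see [aa_composition()]); candidate assemblies must agree
#'   with them, counting the Leu/Ile and Lys/Gln pools jointly since the
#'   spectra cannot separate those pairs. This rejects near-isobaric
#'   compositional misreadings (e.g. Gly+Val for Arg) that pass the intact
#'   mass check.
#' @return object of class `crp_assembly` with elements `consensus`,
#'   `sequences` (all mass-consistent consensi), `placements`, `flags`,
#'   `ambiguous`, `consensus_mh`, and `candidates` (every mass-consistent
#'   assembly as its own `crp_assembly`, best first, for downstream
#'   arbitration e.g. against a measured amino-acid composition).
#' @export
assemble_fragments <- function(fragments, intact_mh, mass_tol = 0.7,
                               min_overlap = 1, max_alternatives = 8,
                               max_states = 20000, composition = NULL) {
  if (is.data.frame(fragments))
    fragments <- lapply(seq_len(nrow(fragments)), function(i)
      list(sequence = fragments$sequence[i], enzyme = fragments$enzyme[i]))
  if (!length(fragments)) stop("no fragments to assemble")
  frs <- lapply(fragments, .norm_fragment,
                max_alternatives = max_alternatives)
  nf <- length(frs)
  ord <- order(-vapply(frs, function(f) f$alts[[1]]$n, integer(1)))
  frs <- frs[ord]
  # residue count that the intact mass can possibly accommodate
  max_len <- as.integer((intact_mh + mass_tol - .MASS_H2O) / .AA_MONO[["G"]]) + 1L

  passing <- list()
  any_placed <- FALSE
  any_boundary <- FALSE
  n_visited <- 0L
  budget_after_hit <- 500L
  n_since_hit <- 0L

  evaluate <- function(cover, offsets, alts) {
    for (fi in seq_len(nf)) frs[[fi]]$n_sel <- frs[[fi]]$alts[[alts[fi]]]$n
    any_placed <<- TRUE
    pos <- sort(as.integer(names(cover)))
    shift <- 1L - pos[1]
    letters <- lapply(as.character(pos), function(k) cover[[k]])
    starts <- offsets + shift
    # enzyme boundary rules: a fragment's N-terminus sits at the peptide
    # start or right after a cleavage residue of its enzyme, and its
    # C-terminal residue is itself a cleavage residue or the peptide
    # C-terminus. The C-side rule is what rejects mirrored readings, whose
    # reversal preserves mass and overlaps but not protease specificity.
    n_cons <- length(letters)
    for (fi in seq_len(nf)) {
      s <- starts[fi]
      if (s > 1L &&
          !any(letters[[s - 1L]] %in% frs[[fi]]$enzyme$cleave_after)) return()
      e <- s + frs[[fi]]$n_sel - 1L
      if (e < n_cons &&
          !any(letters[[e]] %in% frs[[fi]]$enzyme$cleave_after)) return()
    }
    any_boundary <<- TRUE
    resolved <- lapply(letters, .set_to_letter)
    cons <- paste(vapply(resolved, `[[`, character(1), "letter"),
                  collapse = "")
    mh <- peptide_mass(peptide(chartr("J", "L", cons)))[["MH"]]  # oxidized
    if (abs(mh - intact_mh) > mass_tol) return()
    if (!is.null(composition) && !.composition_ok(cons, composition)) return()
    key <- paste(cons, paste(starts, collapse = ","), sep = "|")
    if (!is.null(passing[[key]])) return()
    passing[[key]] <<- list(
      consensus = cons, starts = starts, alts = alts, rank = sum(alts),
      consensus_mh = mh,
      flags = data.frame(
        position = seq_along(resolved),
        letter = vapply(resolved, `[[`, character(1), "letter"),
        kq = vapply(resolved, `[[`, logical(1), "kq"),
        ji = vapply(resolved, `[[`, logical(1), "ji")))
  }

  seen <- new.env(parent = emptyenv())
  try_offset <- function(cover, sets, n, o) {
    new_cover <- cover
    for (p in o:(o + n - 1L)) {
      s <- sets[[p - o + 1L]]
      key <- as.character(p)
      if (!is.null(new_cover[[key]])) {
        inter <- intersect(new_cover[[key]], s)
        if (!length(inter)) return(NULL)
        new_cover[[key]] <- inter
      } else new_cover[[key]] <- s
    }
    new_cover
  }
  stop_now <- function() {
    n_visited >= max_states || length(passing) >= 10L ||
      (length(passing) > 0L && n_since_hit >= budget_after_hit)
  }
  place <- function(cover, offsets, alts, placed) {
    if (stop_now()) return()
    sig <- paste(which(placed), alts[placed], offsets[placed],
                 sep = ":", collapse = ";")
    if (!is.null(seen[[sig]])) return()
    seen[[sig]] <- TRUE
    n_visited <<- n_visited + 1L
    if (length(passing)) n_since_hit <<- n_since_hit + 1L
    if (all(placed)) {
      evaluate(cover, offsets, alts)
      return()
    }
    pos <- as.integer(names(cover))
    lo <- min(pos); hi <- max(pos)
    # all consistent overlapping placements of all unplaced fragments,
    # explored best-anchored (longest hull overlap) first
    hits <- list()
    for (fi in which(!placed)) {
      f <- frs[[fi]]
      for (ai in seq_along(f$alts)) {
        alt <- f$alts[[ai]]
        for (o in (lo - alt$n + min_overlap):(hi + 1L - min_overlap)) {
          if (max(hi, o + alt$n - 1L) - min(lo, o) + 1L > max_len) next
          nc <- try_offset(cover, alt$sets, alt$n, o)
          if (!is.null(nc)) {
            ov <- min(hi, o + alt$n - 1L) - max(lo, o) + 1L
            hits[[length(hits) + 1L]] <- list(fi = fi, ai = ai, o = o,
                                              cover = nc, ov = ov)
          }
        }
      }
    }
    if (!length(hits)) {
      # no overlap possible anywhere: abut the longest unplaced fragment
      # (underdetermined order, arbitrated by boundary and mass checks)
      fi <- which(!placed)[1]
      f <- frs[[fi]]
      for (ai in seq_along(f$alts)) {
        alt <- f$alts[[ai]]
        for (o in c(hi + 1L, lo - alt$n)) {
          if (max(hi, o + alt$n - 1L) - min(lo, o) + 1L > max_len) next
          nc <- try_offset(cover, alt$sets, alt$n, o)
          if (!is.null(nc))
            hits[[length(hits) + 1L]] <- list(fi = fi, ai = ai, o = o,
                                              cover = nc, ov = 0L)
        }
      }
    }
    if (!length(hits)) return()
    hits <- hits[order(-vapply(hits, `[[`, integer(1), "ov"),
                       vapply(hits, `[[`, integer(1), "ai"))]
    for (h in hits) {
      offsets2 <- offsets; offsets2[h$fi] <- h$o
      alts2 <- alts; alts2[h$fi] <- h$ai
      placed2 <- placed; placed2[h$fi] <- TRUE
      place(h$cover, offsets2, alts2, placed2)
      if (stop_now()) return()
    }
  }
  for (ai in seq_along(frs[[1]]$alts)) {
    alt <- frs[[1]]$alts[[ai]]
    cover0 <- stats::setNames(alt$sets, as.character(seq_len(alt$n)))
    offsets <- rep(NA_integer_, nf); offsets[1] <- 1L
    alts <- rep(NA_integer_, nf); alts[1] <- ai
    n_visited <- 0L  # fresh state budget per seed interpretation
    place(cover0, offsets, alts, c(TRUE, rep(FALSE, nf - 1L)))
    if (length(passing) >= 10L) break
  }
  if (!length(passing)) {
    if (!any_placed)
      stop("assembly conflict: fragments cannot be placed consistently")
    if (!any_boundary)
      stop("assembly conflict: no placement satisfies the enzyme boundary rule")
    stop(sprintf("mass mismatch: no consensus within %.2f Da of intact [M+H]+ %.2f",
                 mass_tol, intact_mh))
  }
  # prefer assemblies built from the highest-ranked candidates
  passing <- passing[order(vapply(passing, `[[`, numeric(1), "rank"))]
  seqs <- unique(vapply(passing, `[[`, character(1), "consensus"))
  best <- passing[[1]]
  alternates <- lapply(unname(passing), function(p)
    structure(list(consensus = p$consensus, flags = p$flags,
                   ambiguous = FALSE, intact_mh = intact_mh,
                   consensus_mh = p$consensus_mh),
              class = "crp_assembly"))
  placements <- data.frame(
    fragment = vapply(seq_len(nf), function(i) {
      sets <- frs[[i]]$alts[[best$alts[i]]]$sets
      paste(vapply(sets, function(s) .set_to_letter(s)$letter,
                   character(1)), collapse = "")
    }, character(1)),
    enzyme = vapply(frs, function(f) f$enzyme$name, character(1)),
    start = best$starts,
    end = best$starts + vapply(seq_len(nf), function(i)
      frs[[i]]$alts[[best$alts[i]]]$n, integer(1)) - 1L)
  structure(list(consensus = best$consensus, sequences = seqs,
                 placements = placements, flags = best$flags,
                 ambiguous = length(seqs) > 1L, candidates = alternates,
                 intact_mh = intact_mh, consensus_mh = best$consensus_mh),
            class = "crp_assembly")
}

#' @export
print.crp_assembly <- function(x, ...) {
  cat(sprintf("crp_assembly: %s\n  [M+H]+ theor %.4f vs intact %.4f%s\n",
              x$consensus, x$consensus_mh, x$intact_mh,
              if (x$ambiguous) sprintf(" (%d alternative orderings)",
                                       length(x$sequences)) else ""))
  invisible(x)
}

#' Resolve Lys/Gln and Leu/Ile by complete-digest evidence
#'
#' The isobaric pairs cannot be separated by fragment mass at MALDI-TOF/TOF
#' accuracy, but they change enzyme specificity: trypsin cleaves after Lys
#' (not Gln) and chymotrypsin after Leu (not Ile). For each ambiguous
#' position this sets Lys if, and only if, the complete tryptic digest of
#' the hypothesized sequence has a fragment ending at that position whose
#' carbamidomethylated `[M+H]+` matches an observed complete-digest peak
#' (otherwise Gln); Leu/Ile is decided the same way from the complete
#' chymotryptic digest. A first left-to-right sweep uses the N-terminal
#' cleavage product alone; refinement sweeps then demand both products,
#' which removes chance mass collisions. Positions without the relevant
#' peak list stay flagged. The peptide C-terminal residue is never decided
#' here -- the terminal fragment exists whichever isobar is true -- and is
#' left for [resolve_by_composition()], mirroring the role of amino-acid
#' analysis in the wet-lab workflow.
#'
#' @param assembly a `crp_assembly` (or a `seq_candidate`-free list with
#'   `consensus` and `flags`).
#' @param digest_peaks named list with elements `trypsin` and/or
#'   `chymotrypsin`: observed complete-digest peak lists (data.frame or
#'   numeric m/z).
#' @param tol peak-matching tolerance (Da).
#' @return the assembly with resolved `consensus` and an augmented `flags`
#'   table (columns `resolved`, `basis`).
#' @export
resolve_isobaric <- function(assembly, digest_peaks, tol = 0.3) {
  flags <- assembly$flags
  chars <- .seq_chars(assembly$consensus)
  n <- length(chars)
  flags$resolved <- NA
  flags$basis <- NA_character_
  if (!any(flags$kq | flags$ji)) {
    assembly$flags <- flags
    return(assembly)
  }
  get_mz <- function(key) {
    pk <- digest_peaks[[key]]
    if (is.null(pk)) return(NULL)
    .as_peaklist(pk)$mz
  }
  # a supported boundary requires both cleavage products: the fragment
  # ending at the position and (unless terminal) the one starting after it;
  # requiring the pair avoids chance mass collisions with unrelated
  # fragments (e.g. two single-residue Leu fragments)
  support <- function(seq_base, enz, pos, mz, two_sided = TRUE) {
    fr <- digest_complete(seq_base, enz, max_missed = 0, cam = TRUE)
    left <- fr[fr$end == pos, , drop = FALSE]
    if (nrow(left) != 1L || !any(abs(mz - left$mh) <= tol)) return(FALSE)
    if (!two_sided || pos == nchar(seq_base)) return(TRUE)
    right <- fr[fr$start == pos + 1L, , drop = FALSE]
    nrow(right) == 1L && any(abs(mz - right$mh) <= tol)
  }
  decide <- function(which_flag, enz_name, yes, no) {
    mz <- get_mz(enz_name)
    if (is.null(mz)) return()
    idx <- which(flags[[which_flag]])
    if (length(idx) && idx[length(idx)] == n) {
      # the peptide C-terminus has no cleavage products to observe: the
      # terminal complete-digest fragment exists whichever isobar is true.
      # Left for composition-based confirmation (resolve_by_composition).
      flags$basis[n] <<- "unresolved: peptide C-terminus has no cleavage evidence"
      idx <- idx[-length(idx)]
    }
    if (!length(idx)) return()
    # first sweep, left to right with left-fragment evidence only: the
    # fragment ending at p depends solely on already-committed sites
    for (p in idx) {
      hyp <- chars
      hyp[p] <- yes
      hyp[setdiff(idx[idx > p], p)] <- no  # downstream: non-site stand-in
      hyp <- chartr("J", "I", hyp)         # isobaric, never a site
      is_yes <- support(paste(hyp, collapse = ""), enz_name, p, mz,
                        two_sided = FALSE)
      chars[p] <<- if (is_yes) yes else no
    }
    # refinement sweeps with two-sided evidence (both cleavage products),
    # re-evaluating against the current assignment until stable; this
    # removes chance mass collisions of the left fragment alone
    for (sweep in 1:5) {
      changed <- FALSE
      for (p in idx) {
        hyp <- chars
        hyp[p] <- yes
        hyp <- chartr("J", "I", hyp)
        is_yes <- support(paste(hyp, collapse = ""), enz_name, p, mz,
                          two_sided = TRUE)
        new <- if (is_yes) yes else no
        if (new != chars[p]) { chars[p] <<- new; changed <- TRUE }
      }
      if (!changed) break
    }
    for (p in idx) {
      flags$letter[p] <<- chars[p]
      flags[[which_flag]][p] <<- FALSE
      flags$resolved[p] <<- TRUE
      flags$basis[p] <<- sprintf("%s boundary %s", enz_name,
                                 if (chars[p] == yes) "supported" else "absent")
    }
  }
  decide("kq", "trypsin", "K", "Q")
  decide("ji", "chymotrypsin", "L", "I")
  assembly$consensus <- paste(chars, collapse = "")
  assembly$flags <- flags
  if (!is.null(assembly$consensus_mh))
    assembly$consensus_mh <-
      peptide_mass(peptide(chartr("J", "L", assembly$consensus)))[["MH"]]
  assembly
}

#' Confirm remaining isobaric positions by amino-acid composition
#'
#' Amino-acid analysis of the hydrolyzed peptide yields residue counts that
#' distinguish Leu from Ile and Lys from Gln globally. Positions that
#' cleavage evidence cannot reach (notably the peptide C-terminus) are
#' settled here whenever the counts determine them: if the measured Leu
#' count requires all remaining `J` positions to be Leu (or none), they are
#' assigned; a mixed requirement is underdetermined and stays flagged.
#' Lys/Gln is handled identically.
#'
#' @param assembly a `crp_assembly`, typically after [resolve_isobaric()].
#' @param composition named residue counts, e.g. from [aa_composition()] of
#'   a reference or from amino-acid analysis.
#' @return the assembly with determined positions assigned.
#' @export
resolve_by_composition <- function(assembly, composition) {
  flags <- assembly$flags
  chars <- .seq_chars(assembly$consensus)
  settle <- function(which_flag, yes, no) {
    idx <- which(flags[[which_flag]])
    if (!length(idx)) return()
    fixed_yes <- sum(chars[-idx] == yes)  # flagged bases don't count
    need <- composition[[yes]] - fixed_yes
    if (need == length(idx)) pick <- rep(yes, length(idx))
    else if (need == 0) pick <- rep(no, length(idx))
    else return()  # underdetermined split: keep flags
    chars[idx] <<- pick
    flags$letter[idx] <<- pick
    flags[[which_flag]][idx] <<- FALSE
    flags$resolved[idx] <<- TRUE
    flags$basis[idx] <<- "amino-acid composition"
  }
  if (is.null(flags$resolved)) flags$resolved <- NA
  if (is.null(flags$basis)) flags$basis <- NA_character_
  settle("ji", "L", "I")
  settle("kq", "K", "Q")
  assembly$consensus <- paste(chars, collapse = "")
  assembly$flags <- flags
  if (!is.null(assembly$consensus_mh) && !any(flags$ji))
    assembly$consensus_mh <-
      peptide_mass(peptide(chartr("J", "L", assembly$consensus)))[["MH"]]
  assembly
}
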