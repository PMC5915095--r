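# Bemis-Murcko scaffolds from SMILES.
#
# No cheminformatics toolkit is available as an R dependency here, so this
# file implements the minimal machinery needed for scaffold work on
# drug-like organic molecules: a SMILES reader (organic subset + bracket
# atoms, branches, ring closures incl. %nn, charges; stereochemistry is
# parsed and discarded), Murcko pruning (ring systems and their connecting
# linkers, retaining atoms attached to the framework by double/triple bonds),
# and a Morgan-style canonical SMILES writer so identical frameworks compare
# equal as text. Aromatic/Kekule notation is preserved as given, not
# re-perceived; inputs should therefore use one convention consistently.

.ORGANIC <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
.AROMATIC_OK <- c("b", "c", "n", "o", "p", "s")

#' Parse a SMILES string into a molecular graph
#'
#' Supports the organic subset, bracket atoms (isotope, charge, explicit H,
#' chirality marks are read and dropped), branches, ring-bond closures
#' (digits and `%nn`), bond symbols `- = # :` (`/` and `\` read as single),
#' and dot-separated fragments. Aromaticity is taken from lowercase notation;
#' an implicit bond between two aromatic atoms is aromatic only when it lies
#' in a ring.
#'
#' @param smiles a single SMILES string.
#' @return list with `atoms` (data.frame `symbol`, `aromatic`, `charge`,
#'   `hcount`) and `bonds` (data.frame `a1`, `a2`, `order`, `aromatic`).
#' @export
parseSmiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, !is.na(smiles))
  chars <- strsplit(smiles, "")[[1]]
  n <- length(chars)
  sym <- character(0); arom <- logical(0); chg <- integer(0); hct <- integer(0)
  b1 <- integer(0); b2 <- integer(0); bord <- integer(0); barom <- logical(0)
  prev <- NA_integer_
  pend_ord <- NA_integer_        # bond symbol waiting for the next atom
  stack <- integer(0)
  rings <- list()                # ring number -> c(atom, pending order)
  i <- 1L

  addAtom <- function(s, aromatic, charge = 0L, h = NA_integer_) {
    sym <<- c(sym, s); arom <<- c(arom, aromatic)
    chg <<- c(chg, charge); hct <<- c(hct, h)
    idx <- length(sym)
    if (!is.na(prev)) {
      ord <- if (is.na(pend_ord)) 0L else pend_ord   # 0 = implicit
      b1 <<- c(b1, prev); b2 <<- c(b2, idx)
      bord <<- c(bord, ord); barom <<- c(barom, FALSE)
    }
    prev <<- idx
    pend_ord <<- NA_integer_
    idx
  }
  closeRing <- function(num) {
    key <- as.character(num)
    if (is.null(rings[[key]])) {
      rings[[key]] <<- c(prev, if (is.na(pend_ord)) 0L else pend_ord)
    } else {
      open <- rings[[key]]
      ord <- if (!is.na(pend_ord)) pend_ord
             else if (open[2] != 0L) open[2] else 0L
      b1 <<- c(b1, open[1]); b2 <<- c(b2, prev)
      bord <<- c(bord, ord); barom <<- c(barom, FALSE)
      rings[[key]] <<- NULL
    }
    pend_ord <<- NA_integer_
  }

  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unclosed bracket atom in SMILES: ", smiles)
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      body <- gsub("^[0-9]+", "", body)          # isotope
      body <- gsub("@+", "", body)               # chirality
      m <- regexpr("^[A-Z][a-z]?|^[a-z]", body)
      if (m == -1L) stop("cannot parse bracket atom [", body, "]")
      s <- regmatches(body, m)
      rest <- substring(body, attr(m, "match.length") + 1L)
      aromatic <- s %in% .AROMATIC_OK
      if (aromatic) s <- paste0(toupper(substring(s, 1, 1)), substring(s, 2))
      h <- 0L
      hm <- regexpr("H[0-9]*", rest)
      if (hm != -1L) {
        hs <- sub("H", "", regmatches(rest, hm))
        h <- if (hs == "") 1L else as.integer(hs)
        rest <- sub("H[0-9]*", "", rest)
      }
      charge <- 0L
      cm <- regexpr("[+-][0-9]*[+-]*", rest)
      if (cm != -1L) {
        cs <- regmatches(rest, cm)
        signc <- if (substring(cs, 1, 1) == "-") -1L else 1L
        num <- gsub("[+-]", "", cs)
        charge <- signc * (if (num == "") nchar(gsub("[^+-]", "", cs)) else
                             as.integer(num))
      }
      addAtom(s, aromatic, charge, h)
      i <- j + 1L
    } else if (ch %in% c("C", "B") && i < n && chars[i + 1L] %in% c("l", "r") &&
               paste0(ch, chars[i + 1L]) %in% c("Cl", "Br")) {
      addAtom(paste0(ch, chars[i + 1L]), FALSE)
      i <- i + 2L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      addAtom(ch, FALSE)
      i <- i + 1L
    } else if (ch %in% .AROMATIC_OK) {
      addAtom(toupper(ch), TRUE)
      i <- i + 1L
    } else if (ch == "-") { pend_ord <- 1L; i <- i + 1L
    } else if (ch == "=") { pend_ord <- 2L; i <- i + 1L
    } else if (ch == "#") { pend_ord <- 3L; i <- i + 1L
    } else if (ch == ":") { pend_ord <- 4L; i <- i + 1L   # explicit aromatic
    } else if (ch %in% c("/", "\\")) { pend_ord <- 1L; i <- i + 1L
    } else if (ch == "(") { stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) stop("unbalanced ')' in SMILES: ", smiles)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      closeRing(as.integer(ch)); i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n) stop("truncated %nn ring closure")
      closeRing(as.integer(paste(chars[(i + 1L):(i + 2L)], collapse = "")))
      i <- i + 3L
    } else if (ch == ".") {
      prev <- NA_integer_; pend_ord <- NA_integer_; i <- i + 1L
    } else {
      stop("unsupported SMILES character '", ch, "' in: ", smiles)
    }
  }
  if (length(rings) > 0L) stop("unclosed ring bond in SMILES: ", smiles)
  if (length(stack) > 0L) stop("unbalanced '(' in SMILES: ", smiles)
  if (length(sym) == 0L) stop("empty SMILES")

  atoms <- data.frame(symbol = sym, aromatic = arom, charge = chg,
                      hcount = hct, stringsAsFactors = FALSE)
  bonds <- data.frame(a1 = b1, a2 = b2, order = bord, aromatic = FALSE)
  mol <- list(atoms = atoms, bonds = bonds)
  .resolveBondTypes(mol)
}

# decide implicit bond orders: between two aromatic atoms a ring bond is
# aromatic, otherwise single; ':' is always aromatic
.resolveBondTypes <- function(mol) {
  b <- mol$bonds
  if (nrow(b) == 0L) return(mol)
  arom_pair <- mol$atoms$aromatic[b$a1] & mol$atoms$aromatic[b$a2]
  explicit_arom <- b$order == 4L
  implicit <- b$order == 0L
  in_ring <- vapply(seq_len(nrow(b)), function(i) {
    if (!implicit[i] || !arom_pair[i]) return(FALSE)
    .bondInRing(mol, i)
  }, logical(1))
  b$aromatic <- explicit_arom | (implicit & arom_pair & in_ring)
  b$order[b$aromatic] <- 1L
  b$order[b$order == 0L] <- 1L
  mol$bonds <- b
  mol
}

# is bond i part of a cycle? endpoints stay connected after removing it
.bondInRing <- function(mol, i) {
  b <- mol$bonds[-i, , drop = FALSE]
  from <- mol$bonds$a1[i]; to <- mol$bonds$a2[i]
  seen <- from
  frontier <- from
  while (length(frontier) > 0L) {
    nb <- c(b$a2[b$a1 %in% frontier], b$a1[b$a2 %in% frontier])
    frontier <- setdiff(nb, seen)
    if (to %in% frontier) return(TRUE)
    seen <- c(seen, frontier)
  }
  FALSE
}

.adjacency <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- vector("list", n)
  for (i in seq_len(nrow(mol$bonds))) {
    a <- mol$bonds$a1[i]; b <- mol$bonds$a2[i]
    adj[[a]] <- c(adj[[a]], i); adj[[b]] <- c(adj[[b]], i)
  }
  adj
}

# Murcko framework atom set: the 2-core (rings + connecting linkers) plus
# atoms attached to it by a double or triple bond (exocyclic carbonyls etc.)
.murckoAtoms <- function(mol) {
  n <- nrow(mol$atoms)
  if (n == 0L || nrow(mol$bonds) == 0L) return(integer(0))
  alive <- rep(TRUE, n)
  deg <- tabulate(c(mol$bonds$a1, mol$bonds$a2), nbins = n)
  repeat {
    drop <- which(alive & deg <= 1L)
    if (length(drop) == 0L) break
    alive[drop] <- FALSE
    for (i in seq_len(nrow(mol$bonds))) {
      a <- mol$bonds$a1[i]; b <- mol$bonds$a2[i]
      if (a %in% drop && alive[b]) deg[b] <- deg[b] - 1L
      if (b %in% drop && alive[a]) deg[a] <- deg[a] - 1L
    }
    deg[drop] <- 0L
  }
  core <- which(alive)
  if (length(core) == 0L) return(integer(0))
  multi <- mol$bonds$order >= 2L
  addback <- unique(c(
    mol$bonds$a2[multi & mol$bonds$a1 %in% core & !(mol$bonds$a2 %in% core)],
    mol$bonds$a1[multi & mol$bonds$a2 %in% core & !(mol$bonds$a1 %in% core)]))
  sort(c(core, addback))
}

.inducedSubgraph <- function(mol, keep) {
  idx <- match(seq_len(nrow(mol$atoms)), keep)
  b <- mol$bonds[mol$bonds$a1 %in% keep & mol$bonds$a2 %in% keep, ,
                 drop = FALSE]
  b$a1 <- idx[b$a1]; b$a2 <- idx[b$a2]
  rownames(b) <- NULL
  list(atoms = mol$atoms[keep, , drop = FALSE], bonds = b)
}

# Morgan-style canonical ranks; ties broken by individualisation of the
# lowest-indexed member of the smallest tied class (sound for automorphic
# ties, which is what symmetric drug-like frameworks produce)
.canonicalRanks <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- .adjacency(mol)
  key <- paste(mol$atoms$symbol, mol$atoms$aromatic, mol$atoms$charge,
               vapply(adj, length, integer(1)))
  rank <- match(key, sort(unique(key)))
  refine <- function(rank) {
    repeat {
      key <- vapply(seq_len(n), function(a) {
        nb <- vapply(adj[[a]], function(bi) {
          other <- if (mol$bonds$a1[bi] == a) mol$bonds$a2[bi] else
            mol$bonds$a1[bi]
          sprintf("%d:%d:%d", mol$bonds$order[bi],
                  as.integer(mol$bonds$aromatic[bi]), rank[other])
        }, character(1))
        paste(rank[a], paste(sort(nb), collapse = ","))
      }, character(1))
      new <- match(key, sort(unique(key)))
      if (length(unique(new)) == length(unique(rank))) return(new)
      rank <- new
    }
  }
  rank <- refine(rank)
  while (length(unique(rank)) < n) {
    tied <- which(tabulate(rank) > 1L)[1L]
    pick <- which(rank == tied)[1L]
    rank <- rank * 2L
    rank[pick] <- rank[pick] - 1L
    rank <- match(rank, sort(unique(rank)))
    rank <- refine(rank)
  }
  rank
}

.atomToken <- function(mol, a) {
  s <- mol$atoms$symbol[a]
  aromatic <- mol$atoms$aromatic[a]
  charge <- mol$atoms$charge[a]
  h <- mol$atoms$hcount[a]
  body <- if (aromatic) tolower(s) else s
  plain <- charge == 0L && is.na(h) &&
    s %in% .ORGANIC && (!aromatic || tolower(s) %in% .AROMATIC_OK)
  if (plain) return(body)
  hs <- if (!is.na(h) && h > 0L) paste0("H", if (h > 1L) h else "") else ""
  cs <- if (charge > 0L) paste0("+", if (charge > 1L) charge else "")
        else if (charge < 0L) paste0("-", if (charge < -1L) -charge else "")
        else ""
  paste0("[", body, hs, cs, "]")
}

.bondToken <- function(mol, bi) {
  if (mol$bonds$aromatic[bi]) return("")
  ord <- mol$bonds$order[bi]
  if (ord == 2L) return("=")
  if (ord == 3L) return("#")
  # explicit single between two aromatic atoms (e.g. biphenyl link)
  if (mol$atoms$aromatic[mol$bonds$a1[bi]] &&
      mol$atoms$aromatic[mol$bonds$a2[bi]]) return("-")
  ""
}

# write one connected component rooted at `root` given canonical ranks
.writeComponent <- function(mol, adj, rank, root) {
  visited <- rep(FALSE, nrow(mol$atoms))
  used_bond <- rep(FALSE, nrow(mol$bonds))
  ring_num <- 0L
  ring_at <- lapply(seq_len(nrow(mol$atoms)), function(i) character(0))

  # pass 1: DFS to find tree/back edges and assign ring-closure digits
  order_children <- function(a, from_bond) {
    bis <- adj[[a]]
    bis <- bis[bis != from_bond | is.na(from_bond)]
    others <- vapply(bis, function(bi)
      if (mol$bonds$a1[bi] == a) mol$bonds$a2[bi] else mol$bonds$a1[bi],
      integer(1))
    bis[order(rank[others])]
  }
  emit <- function(a, from_bond) {
    visited[a] <<- TRUE
    for (bi in order_children(a, from_bond)) {
      if (used_bond[bi]) next
      other <- if (mol$bonds$a1[bi] == a) mol$bonds$a2[bi] else
        mol$bonds$a1[bi]
      if (visited[other]) {                       # back edge -> ring closure
        used_bond[bi] <<- TRUE
        ring_num <<- ring_num + 1L
        d <- if (ring_num <= 9L) as.character(ring_num)
             else sprintf("%%%02d", ring_num)
        tok <- paste0(.bondToken(mol, bi), d)
        ring_at[[a]] <<- c(ring_at[[a]], tok)
        ring_at[[other]] <<- c(ring_at[[other]], tok)
      }
    }
    parts <- character(0)
    kids <- Filter(function(bi) !used_bond[bi], order_children(a, from_bond))
    for (bi in kids) {
      if (used_bond[bi]) next
      other <- if (mol$bonds$a1[bi] == a) mol$bonds$a2[bi] else
        mol$bonds$a1[bi]
      if (visited[other]) next
      used_bond[bi] <<- TRUE
      parts <- c(parts, paste0(.bondToken(mol, bi), emit(other, bi)))
    }
    core <- paste0(.atomToken(mol, a), paste(ring_at[[a]], collapse = ""))
    if (length(parts) == 0L) return(core)
    wrapped <- c(vapply(parts[-length(parts)],
                        function(p) paste0("(", p, ")"), character(1)),
                 parts[length(parts)])
    paste0(core, paste(wrapped, collapse = ""))
  }
  emit(root, NA_integer_)
}

#' Canonical SMILES of a parsed molecule or SMILES string
#'
#' Canonicalisation is self-consistent within this package (Morgan-style
#' ranks + deterministic DFS): two SMILES describe the same framework iff
#' their canonical strings are equal. It does not aim to reproduce any other
#' toolkit's canonical output. Stereochemistry is dropped; disconnected
#' fragments are sorted and joined with `.`.
#'
#' @param x a SMILES string or the result of [parseSmiles()].
#' @return canonical SMILES string.
#' @export
canonicalSmiles <- function(x) {
  mol <- if (is.character(x)) parseSmiles(x) else x
  n <- nrow(mol$atoms)
  rank <- .canonicalRanks(mol)
  adj <- .adjacency(mol)
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (a in seq_len(n)) {
    if (!is.na(comp[a])) next
    k <- k + 1L
    frontier <- a
    while (length(frontier) > 0L) {
      comp[frontier] <- k
      nb <- unlist(lapply(frontier, function(u) {
        bis <- adj[[u]]
        vapply(bis, function(bi)
          if (mol$bonds$a1[bi] == u) mol$bonds$a2[bi] else mol$bonds$a1[bi],
          integer(1))
      }))
      frontier <- unique(nb[is.na(comp[nb])])
    }
  }
  frags <- vapply(seq_len(k), function(ci) {
    members <- which(comp == ci)
    root <- members[which.min(rank[members])]
    .writeComponent(mol, adj, rank, root)
  }, character(1))
  paste(sort(frags), collapse = ".")
}

#' Bemis-Murcko scaffold of a molecule
#'
#' The scaffold is the molecule's ring systems plus the linkers connecting
#' them: all terminal side-chain atoms are iteratively removed, while atoms
#' attached to the remaining framework by a double or triple bond (e.g.
#' exocyclic carbonyl oxygens) are retained. Atom and bond types are
#' preserved (classic typed Bemis-Murcko, not the carbon-skeleton variant);
#' stereochemistry is stripped. The result is canonicalised with
#' [canonicalSmiles()] so identical frameworks compare equal as text.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical scaffold SMILES; `""` for acyclic
#'   molecules, `NA` (with a warning) for unparseable input.
#' @examples
#' murckoScaffold("Cc1ccccc1")   # toluene -> benzene
#' murckoScaffold("CCCCCC")     # n-hexane -> "" (no ring)
#' @export
murckoScaffold <- function(smiles) {
  out <- vapply(smiles, function(s) {
    if (is.na(s)) return(NA_character_)
    if (!nzchar(s)) return("")     # empty scaffold is a fixed point
    mol <- tryCatch(parseSmiles(s), error = function(e) NULL)
    if (is.null(mol)) return(NA_character_)
    keep <- .murckoAtoms(mol)
    if (length(keep) == 0L) return("")
    canonicalSmiles(.inducedSubgraph(mol, keep))
  }, character(1), USE.NAMES = FALSE)
  if (anyNA(out))
    warning(sum(is.na(out)), " structure(s) could not be parsed; skipped")
  out
}

#' Scaffold frequency distribution of a cohort
#'
#' Groups structures by canonical Murcko scaffold and reports counts and
#' percentages of the cohort (denominator = successfully parsed structures).
#' Acyclic molecules are reported under an explicit empty-scaffold bucket
#' (`scaffold = ""`) rather than dropped; unparseable structures are skipped
#' with a warning.
#'
#' @param smiles character vector of SMILES strings.
#' @param cohort_label optional label recorded in a `cohort` column.
#' @return data.frame with columns `scaffold`, `n`, `pct` (and `cohort` when
#'   labelled), sorted by descending `pct`, ties by scaffold text.
#' @export
scaffoldDistribution <- function(smiles, cohort_label = NULL) {
  if (length(smiles) == 0L)
    return(data.frame(scaffold = character(0), n = integer(0),
                      pct = numeric(0), stringsAsFactors = FALSE))
  sc <- murckoScaffold(smiles)
  sc <- sc[!is.na(sc)]
  if (length(sc) == 0L)
    return(data.frame(scaffold = character(0), n = integer(0),
                      pct = numeric(0), stringsAsFactors = FALSE))
  tab <- table(sc)
  out <- data.frame(scaffold = names(tab), n = as.integer(tab),
                    pct = 100 * as.integer(tab) / length(sc),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$pct, out$scaffold), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(cohort_label)) out$cohort <- cohort_label
  out
}
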