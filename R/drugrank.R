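#' Deterministic k-mer overlap stub scorer
#'
#' A compound-protein scorer used only for tests and demonstrations of
#' the ranking pipeline: the SMILES string is tokenised into character
#' 3-grams hashed into a fixed vocabulary ("pseudo-pharmacophore"
#' tokens), the protein into 3-mers hashed into the same vocabulary, and
#' the score is the number of protein 3-mers whose hash falls in the
#' compound's token set. It is
#' deterministic for fixed inputs and has no chemistry in it; real
#' sequence-based interaction models plug in through the same
#' \code{function(smiles, sequence)} contract.
#'
#' @param vocab_size hash vocabulary size.
#' @return A scorer \code{function(smiles, sequence) -> numeric}.
#' @examples
#' scorer <- kmerStubScorer()
#' scorer("CCO", "MKTAYIAKQR")
#' @export
kmerStubScorer <- function(vocab_size = 4096L) {
  hash <- function(s) {
    ## polynomial rolling hash over ASCII codes, deterministic across R runs
    vapply(s, function(tok) {
      h <- 0
      for (cc in utf8ToInt(tok)) h <- (h * 131 + cc) %% vocab_size
      h
    }, numeric(1), USE.NAMES = FALSE)
  }
  ngrams <- function(s, k) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
  }
  function(smiles, sequence) {
    tokens <- unique(hash(ngrams(smiles, 3L)))
    kmers <- hash(ngrams(sequence, 3L))
    sum(kmers %in% tokens)
  }
}

#' Single-residue deletion scan over a functional interval
#'
#' Scores every compound against the full sequence (reference) and
#' against each single-residue deletion variant across the interval, to
#' show how stable each compound's predicted interaction is to small
#' perturbations of the functional sequence.
#'
#' @param sequence protein amino-acid string.
#' @param interval a \linkS4class{FunctionalInterval} or
#'   \code{c(start, end)} (1-based inclusive, within the sequence).
#' @param compounds data.frame with \code{compound_id} and \code{smiles}.
#' @param scorer \code{function(smiles, sequence) -> numeric}.
#' @return numeric matrix, compounds x (reference + one column per
#'   deleted position, named \code{ref, del_<pos>}); scorer failures are
#'   recorded as NA.
#' @export
deletionScan <- function(sequence, interval, compounds, scorer) {
  se <- if (is(interval, "FunctionalInterval"))
    c(interval@start, interval@end) else as.integer(interval)
  if (se[1] < 1 || se[2] > nchar(sequence) || se[1] > se[2])
    stop("interval must lie within the sequence")
  pos <- se[1]:se[2]
  variants <- c(list(ref = sequence),
                setNames(lapply(pos, function(p)
                  paste0(substr(sequence, 1, p - 1),
                         substr(sequence, p + 1, nchar(sequence)))),
                  paste0("del_", pos)))
  out <- matrix(NA_real_, nrow(compounds), length(variants),
                dimnames = list(compounds$compound_id, names(variants)))
  for (i in seq_len(nrow(compounds)))
    for (j in seq_along(variants))
      out[i, j] <- tryCatch(scorer(compounds$smiles[i], variants[[j]]),
                            error = function(e) NA_real_)
  out
}

#' Rank compounds by interaction score
#'
#' Descending-score ranking with ties broken by compound id
#' (lexicographic, flagged) and percentile = 100 * rank / N.
#'
#' @param scores named numeric vector (names = compound ids) or
#'   data.frame with \code{compound_id} and \code{score}.
#' @return data.frame(compound_id, score, rank, percentile, tie) sorted
#'   by rank.
#' @export
rankCompounds <- function(scores) {
  if (is.data.frame(scores)) {
    ids <- scores$compound_id; sc <- scores$score
  } else {
    ids <- names(scores); sc <- as.numeric(scores)
  }
  if (!length(sc)) stop("no compounds to rank")
  ord <- order(-sc, ids)
  tie <- duplicated(sc) | duplicated(sc, fromLast = TRUE)
  data.frame(compound_id = ids[ord], score = sc[ord],
             rank = seq_along(ord),
             percentile = 100 * seq_along(ord) / length(ord),
             tie = tie[ord], row.names = NULL)
}

#' Compare a compound's rank across sequence contexts
#'
#' Ranks the whole compound library against three contexts derived from
#' one parent protein: the functional region alone, the parent with the
#' functional region excised, and the full protein; reports the focal
#' compounds' rank and percentile in each.
#'
#' @param compound_ids focal compound id(s).
#' @param sequence parent protein string.
#' @param interval functional interval (\linkS4class{FunctionalInterval}
#'   or \code{c(start, end)}).
#' @param compounds compound library data.frame (\code{compound_id},
#'   \code{smiles}).
#' @param scorer \code{function(smiles, sequence) -> numeric}.
#' @return data.frame with one row per focal compound x context:
#'   \code{compound_id, context, score, rank, percentile}.
#' @export
contextComparison <- function(compound_ids, sequence, interval, compounds,
                              scorer) {
  se <- if (is(interval, "FunctionalInterval"))
    c(interval@start, interval@end) else as.integer(interval)
  contexts <- list(
    functional_region = substr(sequence, se[1], se[2]),
    region_removed = paste0(substr(sequence, 1, se[1] - 1),
                            substr(sequence, se[2] + 1, nchar(sequence))),
    full_protein = sequence)
  out <- list()
  for (ctx in names(contexts)) {
    sc <- vapply(compounds$smiles, scorer, numeric(1),
                 sequence = contexts[[ctx]], USE.NAMES = FALSE)
    rk <- rankCompounds(data.frame(compound_id = compounds$compound_id,
                                   score = sc))
    hit <- rk[rk$compound_id %in% compound_ids, ]
    out[[ctx]] <- data.frame(compound_id = hit$compound_id, context = ctx,
                             score = hit$score, rank = hit$rank,
                             percentile = hit$percentile)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read a compound library CSV
#' @param path CSV with columns \code{compound_id, smiles}.
#' @return data.frame.
#' @export
readCompoundLibrary <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("compound_id", "smiles") %in% names(df)))
    stop("compound CSV needs 'compound_id' and 'smiles' columns")
  df
}
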