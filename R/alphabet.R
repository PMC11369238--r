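#' The 33-symbol token alphabet
#'
#' The model emits a distribution over a fixed 33-symbol vocabulary in the
#' style of the ESM1b alphabet: four leading specials (`<cls>`, `<pad>`,
#' `<eos>`, `<unk>`), the 20 canonical amino acids, the ambiguity/rare codes
#' `X`, `B`, `U`, `Z`, `O`, the alignment symbols `.` and `-`, a reserved
#' `<null>` token and the trailing `<mask>` token. Token ids are 1-based.
#'
#' @return Character vector of length 33; names are unset, order is the id
#'   order.
#' @export
token_alphabet <- function() {
  c("<cls>", "<pad>", "<eos>", "<unk>",
    "L", "A", "G", "V", "S", "E", "R", "T", "I", "D", "P", "K", "Q", "N",
    "F", "Y", "M", "H", "W", "C",
    "X", "B", "U", "Z", "O", ".", "-", "<null>", "<mask>")
}

# id lookup environment built once at load
.alphabet_env <- new.env(parent = emptyenv())

.token_ids <- function() {
  if (is.null(.alphabet_env$ids)) {
    ab <- token_alphabet()
    ids <- seq_along(ab)
    names(ids) <- ab
    .alphabet_env$ids <- ids
  }
  .alphabet_env$ids
}

#' Special and residue token ids
#'
#' @return Named integer list with `cls`, `pad`, `eos`, `unk`, `null`, `mask`
#'   (special ids) and `aa` (the 20 canonical residue ids, named by letter).
#' @export
token_specials <- function() {
  ids <- .token_ids()
  list(cls  = unname(ids[["<cls>"]]),
       pad  = unname(ids[["<pad>"]]),
       eos  = unname(ids[["<eos>"]]),
       unk  = unname(ids[["<unk>"]]),
       null = unname(ids[["<null>"]]),
       mask = unname(ids[["<mask>"]]),
       aa   = ids[AA_LETTERS])
}

#' Canonical amino-acid one-letter codes (vocabulary order)
#' @export
AA_LETTERS <- c("L", "A", "G", "V", "S", "E", "R", "T", "I", "D",
                "P", "K", "Q", "N", "F", "Y", "M", "H", "W", "C")

#' Tokenize an amino-acid sequence
#'
#' Maps a character string over the 20-letter alphabet (plus `X`) to 1-based
#' token ids. No cls/eos wrappers are added so that token `i` stays aligned
#' with point `i` of the protein point cloud.
#'
#' @param sequence Character scalar, amino-acid letters (case-insensitive).
#' @return Object of class `tok_seq`: list with integer `tokens` and logical
#'   `pad` flags (all `FALSE` here; padding is added by [crop_or_pad()]).
#' @export
tokenize_sequence <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  letters <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(letters), c(AA_LETTERS, "X"))
  if (length(bad) > 0L)
    stop("sequence contains letters outside the 20+X alphabet: ",
         paste(bad, collapse = ", "))
  ids <- .token_ids()
  tok_seq(unname(ids[letters]))
}

#' Construct a tokenized sequence from raw ids
#' @param tokens Integer vector of token ids in `[1, 33]`.
#' @param pad Logical vector of pad flags (default all `FALSE`).
#' @export
tok_seq <- function(tokens, pad = rep(FALSE, length(tokens))) {
  tokens <- as.integer(tokens)
  stopifnot(length(tokens) >= 1L, all(tokens >= 1L & tokens <= 33L),
            length(pad) == length(tokens))
  structure(list(tokens = tokens, pad = as.logical(pad)), class = "tok_seq")
}

#' @export
print.tok_seq <- function(x, ...) {
  cat(sprintf("<tok_seq> %d tokens (%d padded)\n",
              length(x$tokens), sum(x$pad)))
  invisible(x)
}

#' Map token ids back to symbols
#' @param tokens Integer vector of ids.
#' @export
detokenize <- function(tokens) token_alphabet()[as.integer(tokens)]
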