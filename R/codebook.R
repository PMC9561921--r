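#' Default 40-character speller charset
#'
#' The speller operates on 40 symbols arranged in 8 groups of 5. The default
#' set is the 26 letters, the 10 digits and four punctuation symbols, in
#' reading order so that the first group is A-E.
#'
#' @return Character vector of length 40.
#' @export
default_charset <- function() {
  c(LETTERS, as.character(0:9), ".", "?", "!", "_")
}

# Default assignment of the eight 3-bit SDMA codes to groups in reading
# order. The A-E group must carry "101"; the remaining order is a fixed
# package convention (all 8 codes over the 3-bit space are used).
.default_codes <- c("101", "011", "110", "111", "001", "010", "100", "000")

.default_layout <- c(
  "top-left", "top-center", "top-right",
  "mid-left", "mid-right",
  "bottom-left", "bottom-center", "bottom-right"
)

#' Build the SDMA speller codebook
#'
#' Partitions a 40-symbol charset into 8 ordered groups of 5 and assigns
#' each group a distinct 3-bit SDMA code. Bit k of a group's code says
#' whether that group emits a motion-onset stimulus in stage-1 sub-trial k.
#'
#' @param charset Character vector of exactly 40 unique symbols
#'   (default [default_charset()]). Groups are consecutive quintets.
#' @param codes Character vector of 8 distinct 3-bit strings assigned to
#'   groups in order. The default honours the published "101" code for the
#'   group containing 'A'.
#' @param layout Character vector of 8 screen-position labels (metadata
#'   only; nothing is rendered).
#' @return An object of class `speller_codebook`: a list with `groups`
#'   (8 x 5 character matrix, one row per group), `codes`, `layout` and
#'   `charset`.
#' @examples
#' cb <- build_codebook()
#' cb$codes[[1]]  # "101" for the A-E group
#' @export
build_codebook <- function(charset = default_charset(),
                           codes = .default_codes,
                           layout = .default_layout) {
  charset <- as.character(charset)
  if (length(charset) != 40L || anyDuplicated(charset)) {
    stop("`charset` must contain exactly 40 unique symbols", call. = FALSE)
  }
  codes <- as.character(codes)
  if (length(codes) != 8L || anyDuplicated(codes) ||
      !all(grepl("^[01]{3}$", codes))) {
    stop("`codes` must be 8 distinct 3-bit binary strings", call. = FALSE)
  }
  if (length(layout) != 8L) {
    stop("`layout` must have 8 position labels", call. = FALSE)
  }
  groups <- matrix(charset, nrow = 8L, ncol = 5L, byrow = TRUE,
                   dimnames = list(paste0("group", 1:8), NULL))
  structure(
    list(groups = groups, codes = codes, layout = layout, charset = charset),
    class = "speller_codebook"
  )
}

#' @export
print.speller_codebook <- function(x, ...) {
  cat("SDMA speller codebook: 8 groups x 5 characters\n")
  for (g in seq_len(8L)) {
    cat(sprintf("  group %d [%s] code %s: %s\n", g, x$layout[g], x$codes[g],
                paste(x$groups[g, ], collapse = " ")))
  }
  invisible(x)
}

#' Encode a character to its group, code and within-group index
#'
#' @param char Single symbol present in the codebook's charset.
#' @param codebook A [build_codebook()] object.
#' @return List with `group` (1-8), `code` (3-bit string) and `within`
#'   (1-5, the symbol's slot inside its group).
#' @examples
#' encode_character("A", build_codebook())  # group 1, code "101", within 1
#' @export
encode_character <- function(char, codebook) {
  stopifnot(inherits(codebook, "speller_codebook"))
  hit <- which(codebook$groups == char, arr.ind = TRUE)
  if (nrow(hit) != 1L) {
    stop(sprintf("character '%s' is not in the codebook charset", char),
         call. = FALSE)
  }
  list(group = unname(hit[1L, "row"]), code = codebook$codes[hit[1L, "row"]],
       within = unname(hit[1L, "col"]))
}

#' Decode a (group, within-group) decision back to a character
#'
#' @param group Group index 1-8.
#' @param within Within-group index 1-5.
#' @param codebook A [build_codebook()] object.
#' @return The spelled symbol.
#' @export
decode_character <- function(group, within, codebook) {
  stopifnot(inherits(codebook, "speller_codebook"),
            group %in% 1:8, within %in% 1:5)
  unname(codebook$groups[group, within])
}

#' Bits of a 3-bit code string as an integer vector
#' @param code A string such as "101".
#' @return Integer vector of length 3.
#' @export
code_bits <- function(code) {
  as.integer(strsplit(code, "")[[1]])
}

# Paradigm timing constants (seconds): a 0.3 s motion-onset stimulus
# followed by a 0.2 s inter-stimulus interval gives a 0.5 s slot.
.stim_duration <- 0.3
.stim_interval <- 0.2
.slot <- .stim_duration + .stim_interval

#' Build the two-stage stimulus schedule for one character
#'
#' Stage 1 presents 3 sub-trials (0.5 s each, 1.5 s total) in which every
#' group whose code has bit k set emits a simultaneous motion-onset
#' stimulus. Stage 2 presents the 5 characters of the decided group one by
#' one in a seeded random order (0.5 s each, 2.5 s total), each with the
#' congruent audio cue.
#'
#' @param char Target symbol.
#' @param codebook A [build_codebook()] object.
#' @param seed Integer seed controlling the stage-2 presentation order.
#' @return A `trial_schedule` list: `char`, `group`, `code`, `within`,
#'   `stage1` (data frame: one row per motion event, columns `subtrial`,
#'   `onset`, `group`), `stage2` (data frame: `slot`, `onset`, `within`,
#'   `char`, `is_target`, `has_audio`), `stage1_span`, `stage2_span`,
#'   `seed`.
#' @export
build_schedule <- function(char, codebook, seed = 1L) {
  enc <- encode_character(char, codebook)
  bits <- vapply(codebook$codes, code_bits, integer(3))  # 3 x 8
  s1 <- do.call(rbind, lapply(1:3, function(k) {
    gs <- which(bits[k, ] == 1L)
    if (!length(gs)) return(NULL)
    data.frame(subtrial = k, onset = (k - 1L) * .slot, group = gs)
  }))
  order5 <- with_seed(seed, sample.int(5L))
  s2 <- data.frame(
    slot = 1:5,
    onset = (0:4) * .slot,
    within = order5,
    char = codebook$groups[enc$group, order5],
    is_target = order5 == enc$within,
    has_audio = TRUE
  )
  structure(
    list(char = char, group = enc$group, code = enc$code,
         within = enc$within, stage1 = s1, stage2 = s2,
         stage1_span = 3 * .slot, stage2_span = 5 * .slot, seed = seed),
    class = "trial_schedule"
  )
}

#' Stimulus presentations needed per character
#'
#' In the two-stage paradigm a character costs 3 stage-1 sub-trials plus 5
#' stage-2 slots = 8 presentations. If both the group and the within-group
#' position were coded in parallel, ceil(log2 8) + ceil(log2 5) = 6
#' presentations would suffice. A conventional row/column matrix speller of
#' the same 40 characters (5 x 8) needs 13 flashes.
#'
#' @param codebook A [build_codebook()] object.
#' @param mode One of "two_stage", "fully_parallel", "matrix".
#' @return Integer presentation count.
#' @export
presentations_per_character <- function(codebook,
                                        mode = c("two_stage",
                                                 "fully_parallel",
                                                 "matrix")) {
  stopifnot(inherits(codebook, "speller_codebook"))
  mode <- match.arg(mode)
  n_groups <- nrow(codebook$groups)
  group_size <- ncol(codebook$groups)
  as.integer(switch(mode,
    two_stage = nchar(codebook$codes[1L]) + group_size,
    fully_parallel = ceiling(log2(n_groups)) + ceiling(log2(group_size)),
    matrix = n_groups + group_size
  ))
}

#' Chance level of the two-stage speller
#'
#' A uniform guess over groups then over within-group positions selects the
#' right character with probability 1 / (8 x 5) = 1/40 = 2.5%.
#'
#' @param codebook A [build_codebook()] object.
#' @return Probability of a correct character under random guessing.
#' @export
chance_level <- function(codebook) {
  stopifnot(inherits(codebook, "speller_codebook"))
  1 / (nrow(codebook$groups) * ncol(codebook$groups))
}
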