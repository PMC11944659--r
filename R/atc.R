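# ATC (anatomical therapeutic chemical) code handling.
#
# Codes follow the WHO pattern: level 1 a single anatomical letter (e.g. N,
# nervous system), level 2 adds two digits (N05), levels 3 and 4 one letter
# each (N05A, N05AH), level 5 two digits (N05AH04).

ATC_LEVEL1 <- c("A", "B", "C", "D", "G", "H", "J", "L", "M", "N", "P", "R",
                "S", "V")

#' Parse and validate an ATC code
#'
#' @param code ATC code string (e.g. `"N"`, `"N05"`, `"N05A"`).
#' @return List with `code`, `level` (1-5), and `parents` (the chain of
#'   prefix codes from level 1 up to, but excluding, the code itself).
#' @export
#' @examples
#' parse_atc("N05A")
parse_atc <- function(code) {
  if (length(code) != 1L || !is.character(code) || !nzchar(code))
    stopf("parse_atc: code must be a non-empty string")
  chars <- strsplit(code, "")[[1]]
  expect <- c("L1", "digit", "digit", "letter", "letter", "digit", "digit")
  if (length(chars) > 7L)
    stopf("malformed ATC code '%s': too long (position 8)", code)
  for (i in seq_along(chars)) {
    ok <- switch(expect[i],
                 L1 = chars[i] %in% ATC_LEVEL1,
                 digit = grepl("^[0-9]$", chars[i]),
                 letter = grepl("^[A-Z]$", chars[i]))
    if (!ok)
      stopf("malformed ATC code '%s' at position %d: expected %s",
            code, i,
            switch(expect[i], L1 = "a level-1 letter (A,B,C,D,G,H,J,L,M,N,P,R,S,V)",
                   digit = "a digit", letter = "an uppercase letter"))
  }
  level_of_len <- c(1L, NA, 2L, 3L, 4L, NA, 5L)
  level <- level_of_len[length(chars)]
  if (is.na(level))
    stopf("malformed ATC code '%s': invalid length %d", code, length(chars))
  lens <- c(1L, 3L, 4L, 5L, 7L)
  parents <- vapply(lens[lens < length(chars)],
                    function(l) substr(code, 1, l), "")
  list(code = code, level = level, parents = parents)
}

#' @rdname parse_atc
#' @export
atc_level <- function(code) parse_atc(code)$level

# Truncate a valid code to the requested level ("" if the code is shallower).
atc_truncate <- function(codes, level) {
  len <- c(1L, 3L, 4L, 5L, 7L)[level]
  out <- substr(codes, 1, len)
  out[nchar(codes) < len] <- ""
  out
}

# Split semicolon-joined code strings into a list of code vectors.
atc_split <- function(atc_codes) {
  lapply(strsplit(atc_codes, ";", fixed = TRUE),
         function(v) v[nzchar(v)])
}
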