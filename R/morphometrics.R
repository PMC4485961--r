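# Wing-area and wing-loading morphometrics.
#
# Inverse wing loading (IWL) is the ratio of a fruit's "long" wing area (cm^2)
# to its air-dried mass (g). Higher IWL means more lift per unit weight and
# longer expected dispersal. The reciprocal quantity, wing loading, is fruit
# weight (as a force, in millidynes) per unit wing area; the descent rate of
# gyrating fruit scales with its square root.

# Standard gravity, cm/s^2; 1 g of mass weighs 980665 millidynes.
.MDYN_PER_GRAM <- 980665

.GENUS_RULES <- c("two_winged", "shorea_five_winged", "wingless")

#' Compute long-wing area of a fruit
#'
#' Wing area follows a genus-specific rule. Two-winged genera (e.g.
#' \emph{Dipterocarpus}, \emph{Hopea}): the sum of length times width over the
#' two wings. Five-winged \emph{Shorea} (three long wings, two short wings,
#' only the longest and shortest long wing measured): the summed rectangular
#' area of the two measured long wings times 1.5, accounting for the unmeasured
#' middle long wing. Short wings contribute negligible lift and never enter the
#' calculation. Wingless fruit have zero wing area.
#'
#' @param genus_rule One of `"two_winged"`, `"shorea_five_winged"`,
#'   `"wingless"`.
#' @param long_wing_lengths Numeric vector of wing lengths (cm): two entries
#'   for `two_winged`, two (longest and shortest long wing) for
#'   `shorea_five_winged`, empty for `wingless`.
#' @param long_wing_widths Numeric vector of wing widths (cm), paired with
#'   `long_wing_lengths`.
#' @return Wing area in cm^2 (a single non-negative number).
#' @examples
#' compute_wing_area("two_winged", c(10, 10), c(3, 3))        # 60
#' compute_wing_area("shorea_five_winged", c(10, 8), c(3, 2.5)) # 75
#' compute_wing_area("wingless", numeric(0), numeric(0))      # 0
#' @export
compute_wing_area <- function(genus_rule, long_wing_lengths, long_wing_widths) {
  genus_rule <- match.arg(genus_rule, .GENUS_RULES)
  if (length(long_wing_lengths) != length(long_wing_widths)) {
    stop("wing length and width lists must have equal length", call. = FALSE)
  }
  if (any(!is.finite(c(long_wing_lengths, long_wing_widths))) ||
      any(c(long_wing_lengths, long_wing_widths) < 0)) {
    stop("wing dimensions must be finite and non-negative", call. = FALSE)
  }
  switch(genus_rule,
    wingless = {
      if (length(long_wing_lengths) != 0L) {
        stop("wingless fruit must have empty wing measurement lists",
             call. = FALSE)
      }
      0
    },
    two_winged = {
      if (length(long_wing_lengths) != 2L) {
        stop("two_winged rule requires exactly two measured wings",
             call. = FALSE)
      }
      sum(long_wing_lengths * long_wing_widths)
    },
    shorea_five_winged = {
      if (length(long_wing_lengths) != 2L) {
        stop("shorea_five_winged rule requires the longest and shortest long wing",
             call. = FALSE)
      }
      sum(long_wing_lengths * long_wing_widths) * 1.5
    }
  )
}

#' Compute inverse wing loading
#'
#' IWL = wing area / mass, in cm^2/g. Zero is a legitimate value (wingless
#' fruit), which is the reason this index is preferred over wing loading
#' itself: wing loading diverges when wing area vanishes.
#'
#' @param wing_area Long-wing area in cm^2 (non-negative).
#' @param mass Fruit air-dried mass in g (strictly positive).
#' @return IWL in cm^2/g.
#' @examples
#' compute_iwl(50, 2) # 25
#' compute_iwl(0, 2.48) # 0, wingless convention
#' @export
compute_iwl <- function(wing_area, mass) {
  if (any(!is.finite(mass)) || any(mass <= 0)) {
    stop("mass must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(wing_area)) || any(wing_area < 0)) {
    stop("wing_area must be finite and >= 0", call. = FALSE)
  }
  wing_area / mass
}

#' Convert inverse wing loading to square-root wing loading
#'
#' Wing loading is fruit weight per wing area: mass converted to a weight in
#' millidynes (1 g weighs 980665 mdyn under standard gravity
#' g = 980.665 cm/s^2) divided by wing area in cm^2, i.e. 980665 / IWL. The
#' descent rate of gyrating fruit is proportional to its square root, so the
#' square-rooted value is returned alongside. For a wingless fruit (IWL = 0)
#' wing loading diverges; both fields are returned as `NA` with an
#' `undefined` flag rather than a number.
#'
#' @param iwl Inverse wing loading in cm^2/g (non-negative; may be vector).
#' @return A data.frame with columns `iwl`, `wing_loading` (mdyn/cm^2),
#'   `sqrt_wing_loading` ((mdyn/cm^2)^(1/2)) and logical `undefined`.
#' @examples
#' iwl_to_sqrt_wing_loading(1)$sqrt_wing_loading # sqrt(980665) ~ 990.285
#' @export
iwl_to_sqrt_wing_loading <- function(iwl) {
  if (any(!is.finite(iwl)) || any(iwl < 0)) {
    stop("iwl must be finite and >= 0", call. = FALSE)
  }
  wl <- ifelse(iwl > 0, .MDYN_PER_GRAM / iwl, NA_real_)
  data.frame(
    iwl = iwl,
    wing_loading = wl,
    sqrt_wing_loading = sqrt(wl),
    undefined = iwl == 0
  )
}

#' Read a fruit morphology table and derive wing area and IWL
#'
#' Reads a CSV with columns `fruit_id,species,genus_rule,wing_lengths_cm,
#' wing_widths_cm,mass_g`, where the wing lists are ';'-separated decimals
#' (empty for wingless fruit), and appends derived columns `wing_area_cm2`
#' and `iwl_cm2_per_g`.
#'
#' @param path Path to the CSV file.
#' @return A data.frame with the input columns plus the two derived columns.
#' @export
read_fruit_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(wing_lengths_cm = "character",
                                      wing_widths_cm = "character"))
  need <- c("fruit_id", "species", "genus_rule", "wing_lengths_cm",
            "wing_widths_cm", "mass_g")
  if (!all(need %in% names(d))) {
    stop("fruit CSV is missing columns: ",
         paste(setdiff(need, names(d)), collapse = ", "), call. = FALSE)
  }
  parse_list <- function(s) {
    if (is.na(s) || !nzchar(s)) numeric(0) else as.numeric(strsplit(s, ";")[[1]])
  }
  d$wing_area_cm2 <- vapply(seq_len(nrow(d)), function(i) {
    compute_wing_area(d$genus_rule[i],
                      parse_list(d$wing_lengths_cm[i]),
                      parse_list(d$wing_widths_cm[i]))
  }, numeric(1))
  d$iwl_cm2_per_g <- compute_iwl(d$wing_area_cm2, d$mass_g)
  d
}

#' Write a fruit morphology table
#'
#' Inverse of [read_fruit_csv()]: serialises wing dimension lists as
#' ';'-separated decimals and writes UTF-8 CSV with '.' decimal separator.
#'
#' @param fruit A data.frame as produced by [generate_fruit()] or
#'   [read_fruit_csv()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fruit_csv <- function(fruit, path) {
  utils::write.csv(fruit, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
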