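#' Amino-acid classification schemes for microenvironment features
#'
#' Six physicochemical classification schemes over the 20 standard amino
#' acids, used to restrict weighted-contact-number (WCN) sums to residues of
#' one class. Schemes: H (hydropathy), V (volume), Z (polarizability),
#' P (polarity), F (charge character), E (chemical group). Within each scheme
#' the classes are disjoint and cover all 20 residues; H, V, Z, P and F have
#' 3 classes each and E has 8, giving 23 class-restricted features.
#'
#' @return Named list of schemes; each scheme is a named list of character
#'   vectors of one-letter residue codes.
#' @examples
#' sch <- aa_schemes()
#' sort(unlist(sch$H, use.names = FALSE)) # the 20 standard residues
#' @export
aa_schemes <- function() {
  split1 <- function(x) strsplit(x, "")[[1]]
  list(
    H = list(pol = split1("RKEDQN"), neu = split1("GASTPHY"), hyd = split1("CVLIMFW")),
    V = list(sma = split1("GASCTPD"), med = split1("NVEQIL"), lar = split1("MHKFRYW")),
    Z = list(low = split1("GASDT"), med = split1("CPNVEQIL"), hig = split1("KMHFRYW")),
    P = list(low = split1("LIFWCMVY"), neu = split1("PATGS"), hig = split1("HQRKNED")),
    F = list(cha = split1("DEHKR"), pol = split1("CGNQSTY"), non = split1("AFILMPVW")),
    E = list(aci = split1("DE"), bas = split1("HKR"), aro = split1("FWY"),
             ami = split1("NQ"), sho = split1("ST"), sul = split1("CM"),
             al1 = split1("AGP"), al2 = split1("ILV"))
  )
}

# the 20 standard one-letter codes, canonical order
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
            GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
            MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
            TYR = "Y", VAL = "V",
            MSE = "M", SEC = "C", PYL = "K")

AA1TO3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
            E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
            M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
            Y = "TYR", V = "VAL")

#' Canonical names of the 45 SAV features
#'
#' The descriptor of one SAV has 45 named features in four fixed-order
#' categories: 3 drug-residue interaction energies (`DKE-ele`, `DKE-hb`,
#' `DKE-vdw`), 26 microenvironment packing densities (`WCN-ca`, `WCN-n`,
#' `WCN-o` plus 23 class-restricted WCNs such as `W-H-neu` or `W-E-aro`),
#' 5 structure features (`BF`, `ACC`, `EHB-acc`, `EHB-don`, `SSE`) and
#' 11 sequence-conservation features (`SSI-b62`, `SSI-p250`, `SSI-pssm`,
#' `ETP-avg1` ... `ETP-avg15`).
#'
#' @param category optional; one of `"energy"`, `"microenv"`, `"structure"`,
#'   `"sequence"` to return just that block's names.
#' @return Character vector of feature names in canonical order.
#' @examples
#' length(feature_names())      # 45
#' feature_names("structure")
#' @export
feature_names <- function(category = NULL) {
  sch <- aa_schemes()
  class_wcn <- unlist(lapply(names(sch), function(s)
    paste0("W-", s, "-", names(sch[[s]]))), use.names = FALSE)
  blocks <- list(
    energy    = c("DKE-ele", "DKE-hb", "DKE-vdw"),
    microenv  = c("WCN-ca", "WCN-n", "WCN-o", class_wcn),
    structure = c("BF", "ACC", "EHB-acc", "EHB-don", "SSE"),
    sequence  = c("SSI-b62", "SSI-p250", "SSI-pssm",
                  paste0("ETP-avg", c(1, 3, 5, 7, 9, 11, 13, 15)))
  )
  if (is.null(category)) return(unlist(blocks, use.names = FALSE))
  if (!category %in% names(blocks))
    stop("unknown feature category: ", category)
  blocks[[category]]
}

# expected block sizes, used by schema validation
BLOCK_SIZES <- c(energy = 3L, microenv = 26L, structure = 5L, sequence = 11L)
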