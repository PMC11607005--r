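# Seed lexicons used to parameterize the per-group character processes.
# These are small, entirely synthetic lists of plausible given names and
# surnames chosen only to give each group distinct character-transition
# statistics (e.g. the kh/gh/ou clusters typical of Arabic- and
# Persian-origin transliterations); they are not a model of any real name
# inventory.
seed_lexicons <- function() {
  list(
    mena = list(
      given = c("khalil", "khaled", "ghassan", "mahmoud", "yusuf", "hassan",
                "ibrahim", "mustafa", "tariq", "samir", "farid", "rashid",
                "karim", "nabil", "omar", "fatima", "khadija", "leila",
                "zahra", "amira", "yasmin", "nadia", "soraya", "mariam",
                "houda", "rania", "ghada", "bashir", "jamil", "adnan"),
      surname = c("khoury", "haddad", "nasser", "ghanem", "saleh", "khalidi",
                  "maalouf", "shadid", "bishara", "hakim", "fakhoury",
                  "sabbagh", "aziz", "mansour", "najjar", "tahan", "zogby",
                  "shaheen", "rahal", "baroudi", "kassem", "ghattas",
                  "boulos", "harb", "dagher", "saliba", "moussa", "attar")
    ),
    white = list(
      given = c("john", "william", "james", "charles", "george", "frank",
                "joseph", "thomas", "henry", "robert", "edward", "harry",
                "walter", "arthur", "mary", "anna", "margaret", "helen",
                "elizabeth", "ruth", "florence", "ethel", "emma", "marie",
                "clara", "bertha", "alice", "mildred", "frances", "dorothy"),
      surname = c("smith", "johnson", "williams", "brown", "jones", "miller",
                  "davis", "wilson", "anderson", "taylor", "thomas", "moore",
                  "martin", "thompson", "white", "harris", "clark", "lewis",
                  "walker", "hall", "young", "allen", "wright", "king",
                  "scott", "green", "baker", "adams", "nelson", "hill")
    ),
    black = list(
      given = c("willie", "james", "john", "robert", "charles", "george",
                "joseph", "samuel", "henry", "walter", "booker", "moses",
                "mary", "annie", "willie mae", "bessie", "mattie", "fannie",
                "carrie", "hattie", "ella", "pearl", "lula", "viola",
                "geneva", "ollie", "essie", "cora", "rosa", "alberta"),
      surname = c("washington", "jefferson", "jackson", "johnson", "williams",
                  "brown", "jones", "davis", "robinson", "harris", "walker",
                  "banks", "freeman", "gaines", "dixon", "booker", "battle",
                  "pettway", "broadnax", "mosley", "ruffin", "tolbert",
                  "leflore", "hairston", "spann", "carruthers", "dozier",
                  "mayweather")
    ),
    api = list(
      given = c("hiroshi", "takeshi", "kazuo", "yoshio", "akira", "kenji",
                "masao", "wing", "kwok", "ming", "cheung", "jin", "sung",
                "young", "chan ho", "yoshiko", "haruko", "fumiko", "kimiko",
                "michiko", "mei", "ling", "siu", "yuen", "sun", "ok cha",
                "myung", "reyes", "felicidad", "consuelo"),
      surname = c("tanaka", "yamamoto", "nakamura", "watanabe", "kobayashi",
                  "saito", "suzuki", "wong", "chan", "lee", "chin", "leong",
                  "fong", "lum", "chang", "kim", "park", "choi", "yoon",
                  "nguyen", "tran", "santos", "reyes", "cruz", "bacani",
                  "delacruz", "mercado", "villanueva")
    ),
    hispanic = list(
      given = c("jose", "juan", "manuel", "francisco", "antonio", "jesus",
                "pedro", "luis", "miguel", "ramon", "salvador", "guadalupe",
                "maria", "juana", "josefina", "carmen", "guadalupe",
                "francisca", "dolores", "soledad", "esperanza", "consuelo",
                "mercedes", "refugio", "trinidad", "margarita", "petra",
                "lupe", "rosario", "amparo"),
      surname = c("garcia", "martinez", "rodriguez", "hernandez", "lopez",
                  "gonzalez", "perez", "sanchez", "ramirez", "torres",
                  "flores", "rivera", "gomez", "diaz", "reyes", "morales",
                  "gutierrez", "ortiz", "chavez", "ramos", "ruiz", "alvarez",
                  "mendoza", "vasquez", "castillo", "jimenez", "moreno",
                  "romero")
    ),
    other = list(
      given = c("ivan", "dmitri", "sergei", "nikolai", "viktor", "boris",
                "janis", "matti", "lars", "sven", "olga", "natasha",
                "ingrid", "astrid", "sigrid", "helga", "katarina", "mirjana",
                "dragan", "zoran", "milos", "vesna", "jadranka", "tamas",
                "istvan", "ferenc", "eino", "toivo", "aino", "kerttu"),
      surname = c("ivanov", "petrov", "kuznetsov", "novak", "horvat",
                  "kovacs", "nagy", "szabo", "lindqvist", "johansson",
                  "nielsen", "hansen", "virtanen", "korhonen", "nieminen",
                  "laakso", "petrovic", "jovanovic", "popov", "sokolov",
                  "marek", "dvorak", "svoboda", "novotny", "varga", "toth",
                  "makinen", "salo")
    )
  )
}

#' Character-transition specification for a name group
#'
#' Builds an order-2 character Markov chain (states are the two previous
#' characters, with start padding and an explicit stop symbol) from a seed
#' lexicon, separately for given names and surnames, with add-k smoothing
#' over the characters seen in the lexicon.
#'
#' @param given,surname character vectors of example names.
#' @param smoothing add-k smoothing constant, default 0.01.
#' @param perturb_rate probability that a generated name receives one
#'   random single-character substitution or adjacent transposition,
#'   emulating transliteration spelling variants. Default 0.15.
#' @return an object of class `name_spec`.
#' @export
name_spec <- function(given, surname, smoothing = 0.01, perturb_rate = 0.15) {
  stopifnot(length(given) > 0, length(surname) > 0)
  build_chain <- function(words) {
    words <- tolower(words)
    alphabet <- sort(unique(c(strsplit(paste(words, collapse = ""), "")[[1]], "$")))
    counts <- new.env(parent = emptyenv())
    for (wd in words) {
      ch <- c("^", "^", strsplit(wd, "")[[1]], "$")
      for (i in 3:length(ch)) {
        st <- paste0(ch[i - 2], ch[i - 1])
        tab <- counts[[st]] %||% stats::setNames(rep(0, length(alphabet)), alphabet)
        tab[ch[i]] <- tab[ch[i]] + 1
        counts[[st]] <- tab
      }
    }
    trans <- lapply(as.list(counts), function(tab) {
      p <- tab + smoothing
      p / sum(p)
    })
    list(trans = trans, alphabet = alphabet)
  }
  structure(list(
    given = build_chain(given), surname = build_chain(surname),
    perturb_rate = perturb_rate
  ), class = "name_spec")
}

# default specs for the six built-in groups
default_name_specs <- function(perturb_rate = 0.15) {
  lapply(seed_lexicons(), function(lx) {
    name_spec(lx$given, lx$surname, perturb_rate = perturb_rate)
  })
}

sample_word <- function(chain, max_len = 14) {
  prev2 <- "^"; prev1 <- "^"
  out <- character(0)
  fallback <- chain$trans[["^^"]]
  repeat {
    st <- paste0(prev2, prev1)
    p <- chain$trans[[st]] %||% fallback
    ch <- sample(names(p), 1, prob = p)
    if (ch == "$" && length(out) >= 2) break
    if (ch == "$") next                      # reject implausibly short names
    out <- c(out, ch)
    if (length(out) >= max_len) break
    prev2 <- prev1; prev1 <- ch
  }
  paste(out, collapse = "")
}

perturb_word <- function(word, alphabet) {
  ch <- strsplit(word, "")[[1]]
  n <- length(ch)
  if (n < 2) return(word)
  if (stats::runif(1) < 0.5) {                     # substitution
    i <- sample.int(n, 1)
    letters_only <- setdiff(alphabet, c("$", " ", "-", "'"))
    ch[i] <- sample(letters_only, 1)
  } else {                                  # adjacent transposition
    i <- sample.int(n - 1, 1)
    ch[c(i, i + 1)] <- ch[c(i + 1, i)]
  }
  paste(ch, collapse = "")
}

#' Generate synthetic name pairs for a group
#'
#' Draws `(given_name, surname)` pairs from the group's order-2 character
#' Markov chains, with a configurable spelling-perturbation rate injecting
#' single-character substitutions/transpositions. Deterministic for a
#' fixed seed.
#'
#' @param group group key; one of the built-in groups (`"mena"`,
#'   `"white"`, `"black"`, `"api"`, `"hispanic"`, `"other"`) or a key into
#'   `specs`.
#' @param n number of pairs.
#' @param seed integer RNG seed; `NULL` uses the current RNG state.
#' @param specs named list of [name_spec()] objects; defaults to the
#'   built-in lexicon-derived specs.
#' @return tibble with columns `given_name`, `surname` (`n` rows).
#' @export
generate_names <- function(group, n, seed = NULL, specs = default_name_specs()) {
  if (!group %in% names(specs)) {
    stop("unknown group '", group, "'; available: ",
         paste(names(specs), collapse = ", "))
  }
  if (!is.null(seed)) set.seed(seed)
  sp <- specs[[group]]
  if (n == 0) {
    return(tibble::tibble(given_name = character(0), surname = character(0)))
  }
  gen <- function(chain) {
    vapply(seq_len(n), function(i) {
      w <- sample_word(chain)
      if (stats::runif(1) < sp$perturb_rate) w <- perturb_word(w, chain$alphabet)
      w
    }, character(1))
  }
  tibble::tibble(given_name = gen(sp$given), surname = gen(sp$surname))
}
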