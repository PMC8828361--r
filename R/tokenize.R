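#' Tokenize tweet text
#'
#' Case-folds, strips hash signs (so hashtags match their plain-word form),
#' and splits on runs of non-alphanumeric characters. Optionally removes
#' stop words and single-character tokens, the normalization used when
#' extracting bigrams.
#'
#' @param text character vector of raw tweet texts.
#' @param drop_stopwords remove stop words (and single-character fragments
#'   left by splitting contractions)? Narrative keyword tagging keeps them so
#'   multi-word patterns see consecutive surface tokens; bigram extraction
#'   drops them.
#' @return list of character token vectors, one per input text.
#' @examples
#' tokenize_text("Thousands of new #covid cases reported in Los Angeles County!!",
#'               drop_stopwords = TRUE)
#' @export
tokenize_text <- function(text, drop_stopwords = FALSE) {
  text <- tolower(text)
  text <- gsub("#", "", text, fixed = TRUE)
  toks <- strsplit(text, "[^a-z0-9]+")
  lapply(toks, function(tk) {
    tk <- tk[nzchar(tk)]
    if (drop_stopwords) {
      tk <- tk[nchar(tk) > 1L & !(tk %in% misinfo_stopwords)]
    }
    tk
  })
}

#' English stop-word list used for bigram and topic preprocessing
#'
#' A fixed list pinned inside the package so tokenization is exactly
#' reproducible across runs and machines. Covers articles, prepositions,
#' pronouns, auxiliaries, and a few high-frequency adverbs; deliberately
#' excludes content words (e.g. "new") so event phrases survive.
#'
#' @format character vector.
#' @export
misinfo_stopwords <- c(
  "a", "an", "the", "and", "or", "but", "nor", "so", "yet", "both",
  "either", "neither", "not", "no", "of", "in", "on", "at", "by", "to",
  "from", "up", "down", "into", "onto", "over", "under", "again",
  "further", "then", "once", "here", "there", "when", "where", "why",
  "how", "all", "any", "each", "few", "more", "most", "other", "some",
  "such", "only", "own", "same", "than", "too", "very", "can", "will",
  "just", "should", "now", "i", "me", "my", "myself", "we", "our",
  "ours", "ourselves", "you", "your", "yours", "yourself", "he", "him",
  "his", "himself", "she", "her", "hers", "herself", "it", "its",
  "itself", "they", "them", "their", "theirs", "themselves", "what",
  "which", "who", "whom", "this", "that", "these", "those", "am", "is",
  "are", "was", "were", "be", "been", "being", "have", "has", "had",
  "having", "do", "does", "did", "doing", "would", "could", "ought",
  "im", "youre", "hes", "shes", "theyre", "ive", "youve", "weve",
  "theyve", "isnt", "arent", "wasnt", "werent", "hasnt", "havent",
  "hadnt", "doesnt", "dont", "didnt", "wont", "wouldnt", "shant",
  "shouldnt", "cant", "cannot", "couldnt", "mustnt", "lets", "thats",
  "whos", "whats", "heres", "theres", "whens", "wheres", "whys", "hows",
  "because", "as", "until", "while", "about", "against", "between",
  "through", "during", "before", "after", "above", "below", "with",
  "without", "if", "for", "rt", "via", "amp"
)
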