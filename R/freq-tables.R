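# Small bundled frequency tables for the synthetic population generator.
# Rank-weighted (Zipf-like) sampling over common Australian-style given
# names, surnames and WA/NSW-flavoured suburb/postcode pairs.  These are
# deliberately small: the generator aims for realistic value collisions
# and name-length distributions, not demographic fidelity.

FIRST_NAMES_F <- c(
  "OLIVIA", "CHARLOTTE", "AMELIA", "MIA", "ISLA", "GRACE", "AVA", "CHLOE",
  "SOPHIE", "ELLA", "MATILDA", "EMILY", "RUBY", "ZOE", "IVY", "LUCY",
  "HANNAH", "SARAH", "EMMA", "LILY", "SIENNA", "ALICE", "GEORGIA", "ANNA",
  "EVELYN", "HARPER", "JESSICA", "MADELEINE", "ABIGAIL", "CLAIRE", "AUDREY",
  "PENELOPE", "STELLA", "HAZEL", "VIOLET", "AURORA", "SAVANNAH", "BROOKLYN",
  "LEAH", "ZARA", "MARGARET", "HELEN", "DOROTHY", "JUDITH", "CAROL",
  "BARBARA", "PATRICIA", "JENNIFER", "LINDA", "ELIZABETH", "MAREE", "KAREN",
  "NICOLE", "MICHELLE", "REBECCA", "KATHERINE", "CHRISTINE", "SUSAN",
  "DEBORAH", "PAMELA")

FIRST_NAMES_M <- c(
  "OLIVER", "WILLIAM", "JACK", "NOAH", "THOMAS", "JAMES", "LUCAS", "HENRY",
  "ETHAN", "MASON", "ALEXANDER", "CHARLIE", "LEO", "HARRISON", "COOPER",
  "MAX", "ISAAC", "SAMUEL", "OSCAR", "LACHLAN", "ELIJAH", "LIAM", "DANIEL",
  "BENJAMIN", "AIDEN", "HUNTER", "JOSHUA", "XAVIER", "PATRICK", "MICHAEL",
  "LEVI", "RYAN", "HUGO", "JACOB", "ARCHIE", "MATTHEW", "LUKE", "ANGUS",
  "NATHAN", "SEBASTIAN", "ROBERT", "JOHN", "DAVID", "RICHARD", "PETER",
  "GEOFFREY", "KENNETH", "RAYMOND", "GREGORY", "BRIAN", "COLIN", "TREVOR",
  "WAYNE", "GARRY", "NEIL", "BARRY", "IAN", "ALAN", "KEITH", "STUART")

LAST_NAMES <- c(
  "SMITH", "JONES", "WILLIAMS", "BROWN", "WILSON", "TAYLOR", "JOHNSON",
  "WHITE", "MARTIN", "ANDERSON", "THOMPSON", "NGUYEN", "THOMAS", "WALKER",
  "HARRIS", "LEE", "RYAN", "ROBINSON", "KELLY", "KING", "DAVIS", "WRIGHT",
  "EVANS", "ROBERTS", "GREEN", "HALL", "WOOD", "JACKSON", "CLARKE",
  "PATEL", "KHAN", "LEWIS", "JAMES", "PHILLIPS", "MASON", "MITCHELL",
  "YOUNG", "TURNER", "HILL", "COOPER", "MORRIS", "WARD", "MOORE", "CLARK",
  "BAKER", "WATSON", "GRAY", "HUGHES", "EDWARDS", "BENNETT", "COLLINS",
  "STEWART", "MURPHY", "BELL", "COOK", "CAMPBELL", "ADAMS", "ALLEN",
  "SCOTT", "CARTER", "OBRIEN", "MCDONALD", "SULLIVAN", "FISHER", "REID",
  "GRANT", "SIMPSON", "BUTLER", "CHAPMAN", "WEBB", "RUSSELL", "GRAHAM",
  "HENDERSON", "MARSHALL", "OWEN", "GIBSON", "FOSTER", "FERGUSON",
  "HAMILTON", "ELLIOTT", "PEARCE", "DUNCAN", "ARMSTRONG", "HUNT", "DIXON",
  "BARNES", "LLOYD", "PALMER", "STONE", "MILLS", "HOLMES", "HART", "LANE",
  "BYRNE", "PORTER", "RICE", "SHAW", "NICHOLLS", "PEARSON", "FRANCIS")

SUBURBS <- c(
  "PERTH", "FREMANTLE", "SUBIACO", "JOONDALUP", "MANDURAH", "BUNBURY",
  "ALBANY", "GERALDTON", "KALGOORLIE", "ROCKINGHAM", "ARMADALE",
  "MIDLAND", "CANNINGTON", "MORLEY", "SCARBOROUGH", "NEDLANDS",
  "SYDNEY", "PARRAMATTA", "NEWCASTLE", "WOLLONGONG", "PENRITH",
  "LIVERPOOL", "BANKSTOWN", "BLACKTOWN", "HORNSBY", "CHATSWOOD",
  "RANDWICK", "MANLY", "DUBBO", "WAGGA WAGGA", "TAMWORTH", "ORANGE",
  "BATHURST", "GOSFORD", "MAITLAND", "CESSNOCK", "BROKEN HILL",
  "LISMORE", "COFFS HARBOUR", "ARMIDALE")

POSTCODES <- c(
  "6000", "6160", "6008", "6027", "6210", "6230",
  "6330", "6530", "6430", "6168", "6112",
  "6056", "6107", "6062", "6019", "6009",
  "2000", "2150", "2300", "2500", "2750",
  "2170", "2200", "2148", "2077", "2067",
  "2031", "2095", "2830", "2650", "2340", "2800",
  "2795", "2250", "2320", "2325", "2880",
  "2480", "2450", "2350")

STREET_NAMES <- c(
  "HIGH", "STATION", "CHURCH", "MAIN", "PARK", "VICTORIA", "ALBERT",
  "GEORGE", "KING", "QUEEN", "ELIZABETH", "WILLIAM", "MARKET", "BEACH",
  "FOREST", "RAILWAY", "SHORT", "LONG", "MILL", "BRIDGE", "RIVER", "LAKE",
  "HILL", "VALLEY", "BROOK", "GARDEN", "ORCHARD", "CHAPEL", "SCHOOL",
  "UNION")

STREET_TYPES <- c("ST", "RD", "AVE", "DR", "CT", "PL", "CRES", "WAY")

# Zipf-ish rank weights: heavy head, long tail of rarer values
rank_weights <- function(n) 1 / seq_len(n)

sample_ranked <- function(pool, n) {
  pool[sample.int(length(pool), n, replace = TRUE,
                  prob = rank_weights(length(pool)))]
}
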