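term,class
angst,negative
flut*,negative
hochwasser,negative
überschwemmung*,negative
wut,negative
wütend,negative
schlecht*,negative
schlimm*,negative
katastrophe*,negative
zerstör*,negative
sorge*,negative
hass,negative
ärger*,negative
panik,negative
verlust*,negative
schaden*,negative
schrecklich*,negative
furchtbar*,negative
krise*,negative
leid*,negative
gefahr*,negative
traurig*,negative
müde,negative
deprimiert*,negative
verzweifelt*,negative
unwetter,negative
gut,positive
super,positive
toll,positive
schön*,positive
froh,positive
glücklich*,positive
freude*,positive
liebe*,positive
danke,positive
wunderbar*,positive
sonnig,positive
lachen*,positive
genial,positive
spaß,positive
herrlich*,positive
entspannt*,positive
der,stopword
die,stopword
das,stopword
und,stopword
oder,stopword
ist,stopword
sind,stopword
ein,stopword
eine,stopword
in,stopword
im,stopword
am,stopword
auf,stopword
mit,stopword
von,stopword
zu,stopword
den,stopword
dem,stopword
des,stopword
es,stopword
ich,stopword
du,stopword
wir,stopword
ihr,stopword
sie,stopword
nicht,stopword
auch,stopword
an,stopword
bei,stopword
für,stopword
war,stopword
wie,stopword
was,stopword
aber,stopword
heute,stopword
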