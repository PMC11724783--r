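pattern,type
no added sugar,nutrition
no added sugars,nutrition
low in sugar,nutrition
low sugar,nutrition
sugar free,nutrition
no added salt,nutrition
low in salt,nutrition
source of vitamin,nutrition
source of vitamins,nutrition
source of minerals,nutrition
source of iron,nutrition
source of calcium,nutrition
source of fibre,nutrition
source of protein,nutrition
high in,nutrition
rich in,nutrition
1 of your 5 a day,nutrition
one of your 5 a day,nutrition
no preservatives,nutrition
no artificial,nutrition
supports healthy growth,health
healthy growth,health
supports development,health
good for,health
aids digestion,health
immune,health
strong bones,health
brain development,health
supports your baby,health
organic,marketing
tasty,marketing
yummy,marketing
delicious,marketing
scrummy,marketing
scrumptious,marketing
perfect for little hands,marketing
little ones love,marketing
kids love,marketing
natural goodness,marketing
made with love,marketing
wholesome,marketing
perfectly balanced,marketing
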