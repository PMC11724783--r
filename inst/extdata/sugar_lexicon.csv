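pattern,class
sugar,added
sucrose,added
glucose,added
dextrose,added
fructose,added
maltose,added
maltodextrin,added
glucose syrup,added
glucose-fructose syrup,added
corn syrup,added
rice syrup,added
brown rice syrup,added
invert sugar,added
golden syrup,added
agave syrup,added
agave nectar,added
maple syrup,added
honey,added
molasses,added
treacle,added
cane juice,added
coconut sugar,added
barley malt extract,added
malt extract,added
sweetener,added
syrup,added
caramel,added
fruit juice,free
apple juice,free
grape juice,free
orange juice,free
lemon juice,free
pear juice,free
juice concentrate,free
fruit juice concentrate,free
apple juice concentrate,free
grape juice concentrate,free
from concentrate,free
concentrated apple,free
concentrated grape,free
fruit concentrate,free
fruit puree powder,free
fruit powder,free
apple powder,free
banana powder,free
date paste,free
raisin paste,free
fruit nectar,free
fruit puree,liberated
apple puree,liberated
pear puree,liberated
banana puree,liberated
mango puree,liberated
strawberry puree,liberated
fruit pulp,liberated
fruit paste,liberated
dried fruit pieces ground,liberated
milk,milk_intrinsic
whole milk,milk_intrinsic
skimmed milk,milk_intrinsic
milk powder,milk_intrinsic
whey,milk_intrinsic
lactose,milk_intrinsic
yogurt,milk_intrinsic
yoghurt,milk_intrinsic
cream,milk_intrinsic
cheese,milk_intrinsic
fromage frais,milk_intrinsic
apple,plant_intrinsic
pear,plant_intrinsic
banana,plant_intrinsic
mango,plant_intrinsic
strawberry,plant_intrinsic
raspberry,plant_intrinsic
blueberry,plant_intrinsic
apricot,plant_intrinsic
peach,plant_intrinsic
raisin,plant_intrinsic
sultana,plant_intrinsic
date,plant_intrinsic
carrot,plant_intrinsic
sweet potato,plant_intrinsic
parsnip,plant_intrinsic
butternut squash,plant_intrinsic
pea,plant_intrinsic
sweetcorn,plant_intrinsic
tomato,plant_intrinsic
beetroot,plant_intrinsic
pumpkin,plant_intrinsic
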