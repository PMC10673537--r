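drug,factor,is_opioid,synonyms,schedule,tier_max_mg,tier_factor
morphine,1,TRUE,ms contin|avinza|kadian|roxanol,II,,
codeine,0.15,TRUE,codeine-acetaminophen|tylenol with codeine|codeine phosphate,II,,
hydrocodone,1,TRUE,norco|vicodin|lortab|hydrocodone-acetaminophen|lorcet,II,,
oxycodone,1.5,TRUE,oxycontin|percocet|roxicodone|oxycodone-acetaminophen|endocet,II,,
hydromorphone,4,TRUE,dilaudid|exalgo,II,,
oxymorphone,3,TRUE,opana,II,,
tapentadol,0.4,TRUE,nucynta,II,,
tramadol,0.1,TRUE,ultram|conzip|tramadol-acetaminophen,IV,,
fentanyl_transdermal,2.4,TRUE,duragesic,II,,
methadone,,TRUE,dolophine|methadose,II,20,4
methadone,,TRUE,,II,40,8
methadone,,TRUE,,II,60,10
methadone,,TRUE,,II,Inf,12
acetaminophen,0,FALSE,tylenol|apap|paracetamol,,,
ibuprofen,0,FALSE,advil|motrin,,,
naproxen,0,FALSE,aleve|naprosyn,,,
aspirin,0,FALSE,bayer|ecotrin,,,
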