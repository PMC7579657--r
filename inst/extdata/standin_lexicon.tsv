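term	concept	item
cancer	cancer_type_superclass	cancer_keyword
malignant tumor	cancer_type_superclass	cancer_keyword
암	cancer_type_superclass	cancer_keyword
carcinoma	cancer_type_superclass	cancer_keyword
hope	hope	HG
hopeful	hope	HG
희망	hope	HG
gratitude	gratitude	HG
grateful	gratitude	HG
thankful	gratitude	HG
감사	gratitude	HG
anxiety	anxiety	FAO
anxious	anxiety	FAO
worried	anxiety	FAO
불안	anxiety	FAO
fear	anxiety	FAO
scared	anxiety	FAO
overwhelmed	overwhelmed	FAO
막막하다	overwhelmed	FAO
sadness	depression	SDLG
sad	depression	SDLG
depressed	depression	SDLG
depression	depression	SDLG
우울	depression	SDLG
lonely	loneliness	SDLG
loneliness	loneliness	SDLG
외로움	loneliness	SDLG
guilt	guilt	SDLG
guilty	guilt	SDLG
죄책감	guilt	SDLG
anger	anger	AD
angry	anger	AD
furious	anger	AD
분노	anger	AD
denial	denial	AD
unbelievable	denial	AD
부정	denial	AD
male	gender	male
man	gender	male
husband	gender	male
female	gender	female
woman	gender	female
wife	gender	female
young child	age	age_under_10
under ten	age	age_under_10
teenager	age	age_10s
teen	age	age_10s
twenties	age	age_20s
20s	age	age_20s
thirties	age	age_30s
30s	age	age_30s
forties	age	age_40s
40s	age	age_40s
fifties	age	age_50s
50s	age	age_50s
sixties	age	age_60s
60s	age	age_60s
seventies	age	age_70s
70s	age	age_70s
eighties	age	age_over_80
over eighty	age	age_over_80
breast cancer	cancer_type	breast_cancer
유방암	cancer_type	breast_cancer
colon cancer	cancer_type	colon_cancer
대장암	cancer_type	colon_cancer
gastric cancer	cancer_type	gastric_cancer
stomach cancer	cancer_type	gastric_cancer
위암	cancer_type	gastric_cancer
leukemia	cancer_type	leukemia
백혈병	cancer_type	leukemia
lung cancer	cancer_type	lung_cancer
폐암	cancer_type	lung_cancer
cervical cancer	cancer_type	cervical_cancer
자궁경부암	cancer_type	cervical_cancer
liver cancer	cancer_type	liver_cancer
간암	cancer_type	liver_cancer
brain cancer	cancer_type	brain_cancer
brain tumor	cancer_type	brain_cancer
뇌종양	cancer_type	brain_cancer
pancreatic cancer	cancer_type	pancreatic_cancer
췌장암	cancer_type	pancreatic_cancer
ovarian cancer	cancer_type	ovarian_cancer
난소암	cancer_type	ovarian_cancer
prostate cancer	cancer_type	prostatic_cancer
전립선암	cancer_type	prostatic_cancer
gallbladder cancer	cancer_type	gallbladder_cancer
담낭암	cancer_type	gallbladder_cancer
kidney cancer	cancer_type	kidney_cancer
신장암	cancer_type	kidney_cancer
thyroid cancer	cancer_type	thyroid_cancer
갑상선암	cancer_type	thyroid_cancer
early stage	cancer_stage	early_stage
stage one	cancer_stage	early_stage
초기	cancer_stage	early_stage
middle stage	cancer_stage	middle_stage
stage two	cancer_stage	middle_stage
terminal stage	cancer_stage	terminal_stage
terminal	cancer_stage	terminal_stage
말기	cancer_stage	terminal_stage
surgery	treatment	surgery
operation	treatment	surgery
수술	treatment	surgery
chemotherapy	treatment	chemotherapy
chemo	treatment	chemotherapy
항암치료	treatment	chemotherapy
radiation therapy	treatment	radiation_therapy
radiotherapy	treatment	radiation_therapy
방사선치료	treatment	radiation_therapy
immunotherapy	treatment	immunotherapy
면역치료	treatment	immunotherapy
alternative medicine	treatment	cam
herbal remedy	treatment	cam
대체요법	treatment	cam
transplant	treatment	transplantation
transplantation	treatment	transplantation
이식	treatment	transplantation
newly diagnosed	survival_stage	acute_survival
just diagnosed	survival_stage	acute_survival
diagnosis	survival_stage	acute_survival
진단	survival_stage	acute_survival
remission	survival_stage	extended_survival
follow-up care	survival_stage	extended_survival
관해	survival_stage	extended_survival
cancer free	survival_stage	permanent_survival
cured	survival_stage	permanent_survival
완치	survival_stage	permanent_survival
fatigue	symptom	fatigue_pain_fever
pain	symptom	fatigue_pain_fever
fever	symptom	fatigue_pain_fever
통증	symptom	fatigue_pain_fever
nausea	symptom	gastrointestinal_problems
vomiting	symptom	gastrointestinal_problems
diarrhea	symptom	gastrointestinal_problems
구토	symptom	gastrointestinal_problems
hair loss	symptom	hair_loss_skin_problems
rash	symptom	hair_loss_skin_problems
itching	symptom	hair_loss_skin_problems
탈모	symptom	hair_loss_skin_problems
numbness	symptom	poor_circulation
cold hands	symptom	poor_circulation
저림	symptom	poor_circulation
bruising	symptom	thrombocytopenia
low platelets	symptom	thrombocytopenia
혈소판감소	symptom	thrombocytopenia
infection	symptom	infection
sepsis	symptom	infection
감염	symptom	infection
computer virus	stop	stop_keyword
horoscope	stop	stop_keyword
zodiac sign	stop	stop_keyword
tropic of cancer	stop	stop_keyword
detoxification	advertising	ad_keyword
miracle cure	advertising	ad_keyword
special discount	advertising	ad_keyword
click here	advertising	ad_keyword
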