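term,concept
chemo,Chemotherapy
chemotherapy,Chemotherapy
chemo treatment,Chemotherapy
adjuvant chemo,Chemotherapy
radiation,Radiation Therapy
rads,Radiation Therapy
radiotherapy,Radiation Therapy
radiation treatment,Radiation Therapy
taxol,Taxol
paclitaxel,Taxol
tamoxifen,Tamoxifen
herceptin,Herceptin
arimidex,Arimidex
mastectomy,Mastectomy
double mastectomy,Bilateral Mastectomy
bilateral mastectomy,Bilateral Mastectomy
lumpectomy,Lumpectomy
reconstruction,Breast Reconstruction
breast reconstruction,Breast Reconstruction
prosthesis,Breast Prosthesis
implant,Breast Implant
implants,Breast Implant
surgery,Surgery
operation,Surgery
biopsy,Biopsy
mammogram,Mammography
mammograms,Mammography
mri,MRI
scan,Imaging Scan
scans,Imaging Scan
pet scan,PET Scan
ultrasound,Ultrasound
bloodwork,Blood Test
blood test,Blood Test
oncologist,Oncologist
oncologists,Oncologist
surgeon,Surgeon
doctor,Physician
doctors,Physician
nurse,Nurse
cancer,Cancer
breast cancer,Breast Cancer
tumor,Tumor
tumour,Tumor
tumors,Tumor
lump,Breast Lump
lumps,Breast Lump
stage,Cancer Stage
triple negative,Triple-Negative Breast Cancer
her2,HER2 Status
er positive,Hormone-Receptor Status
metastatic,Metastasis
metastasis,Metastasis
spread,Metastasis
recurrence,Recurrence
recurred,Recurrence
remission,Remission
prognosis,Prognosis
survival,Survival
diagnosed,Diagnosis
diagnosis,Diagnosis
side effect,Side Effect
side effects,Side Effect
side-effects,Side Effect
nausea,Nausea
vomiting,Vomiting
fatigue,Fatigue
tired,Fatigue
exhausted,Fatigue
pain,Pain
sore,Soreness
soreness,Soreness
ache,Pain
aches,Pain
back pain,Back Pain
breast pain,Breast Pain
headache,Headache
headaches,Headache
swelling,Swelling
swollen,Swelling
lymphedema,Lymphedema
neuropathy,Neuropathy
numbness,Numbness
tingling,Tingling
hair,Hair
hair loss,Alopecia
bald,Alopecia
wig,Wig
wigs,Wig
shampoo,Shampoo
nails,Nail Changes
skin,Skin
rash,Rash
hot flashes,Hot Flashes
night sweats,Night Sweats
insomnia,Insomnia
sleep,Sleep
appetite,Appetite
weight,Body Weight
weight gain,Weight Gain
weight loss,Weight Loss
swallowing,Swallowing
blood pressure,Blood Pressure
bowel,Bowel Function
menopause,Menopause
fertility,Fertility
scared,Fear
scary,Fear
afraid,Fear
fear,Fear
anxiety,Anxiety
anxious,Anxiety
worried,Worry
worry,Worry
depressed,Depression
depression,Depression
sad,Sadness
cry,Crying
crying,Crying
stress,Stress
stressed,Stress
cope,Coping
coping,Coping
counseling,Counseling
therapist,Counseling
support group,Support Group
support groups,Support Group
exercise,Exercise
walking,Exercise
yoga,Yoga
diet,Diet
eat,Diet
eating,Diet
nutrition,Nutrition
vitamins,Vitamins
supplements,Supplements
hydration,Hydration
water,Hydration
rest,Rest
insurance,Insurance
insurance company,Insurance
coverage,Insurance
cost,Cost
costs,Cost
bills,Cost
work,Employment
job,Employment
employer,Employment
family,Family
husband,Spouse
wife,Spouse
kids,Children
children,Children
daughter,Children
son,Children
mom,Parent
mother,Parent
sister,Sibling
friend,Friend
friends,Friend
book,Book
books,Book
website,Website
websites,Website
site,Website
pamphlet,Brochure
brochure,Brochure
brochures,Brochure
article,Article
research,Research
study,Research
mayo,Mayo Clinic
help,Help
experience,Experience
look,Look
looking,Look
normal,Normal
treatment,Treatment
treatments,Treatment
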